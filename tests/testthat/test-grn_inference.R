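make_disc <- function(bins_list, ids, samples = paste0("s", seq_along(bins_list[[1]]))) {
  m <- do.call(rbind, bins_list)
  dimnames(m) <- list(ids, samples)
  structure(list(bins = m,
                 arity = apply(m, 1, function(b) length(unique(b))),
                 n_bins = 3L),
            class = "discretized_matrix")
}

test_that("candidate selection caps at max_candidates by |Pearson r|", {
  set.seed(2)
  n <- 50
  target <- rnorm(n)
  # 12 prior TFs with decreasing correlation to the target
  w <- seq(0.95, 0.05, length.out = 12)
  tf_rows <- lapply(w, function(wi) wi * target + sqrt(1 - wi^2) * rnorm(n))
  m <- rbind(do.call(rbind, tf_rows), target)
  dimnames(m) <- list(c(sprintf("TF%02d", 1:12), "gene"), paste0("s", 1:n))
  prior <- data.frame(tf = sprintf("TF%02d", 1:12), target = "gene")

  cand <- select_candidates("gene", prior, m, inference_config())
  expect_length(cand, 10)
  r <- abs(cor(t(m[sprintf("TF%02d", 1:12), ]), m["gene", ]))[, 1]
  expect_true(max(r[setdiff(names(r), cand)]) <= min(r[cand]))
  # ordered by decreasing |r|
  expect_identical(cand, cand[order(-r[cand])])

  few <- prior[1:4, ]
  expect_length(select_candidates("gene", few, m, inference_config()), 4)
  expect_error(select_candidates("nope", prior, m, inference_config()),
               "target absent")
})

test_that("a gene is never its own candidate unless self-loops are allowed", {
  m <- matrix(rnorm(40), 2, dimnames = list(c("A", "B"), paste0("s", 1:20)))
  prior <- data.frame(tf = c("A", "B"), target = c("A", "A"))
  expect_identical(select_candidates("A", prior, m, inference_config()), "B")
  cand <- select_candidates("A", prior, m,
                            inference_config(allow_self_loops = TRUE))
  expect_setequal(cand, c("A", "B"))
})

test_that("parent-set score: empty set, single-parent reduction, order invariance", {
  cfg <- inference_config(alpha = 0.05)
  set.seed(3)
  tb <- sample(0:2, 90, TRUE)
  p1 <- sample(0:2, 90, TRUE); p2 <- sample(0:2, 90, TRUE)
  p3 <- sample(0:2, 90, TRUE)

  expect_equal(score_parent_set(tb, list(), cfg)$score, 0)

  r1 <- score_parent_set(tb, list(p1), cfg)
  g <- mutual_information(tb, p1)$g_stat
  expect_equal(r1$score, g - chi2_critical(0.05, 4), tolerance = 1e-12)

  # with uniform ternary arity the score is order-invariant
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))
  parents <- list(p1, p2, p3)
  scores <- vapply(perms, function(pm) {
    score_parent_set(tb, parents[pm], cfg)$score
  }, numeric(1))
  expect_equal(max(scores) - min(scores), 0, tolerance = 1e-9)
})

test_that("exhaustive search equals the brute-force argmax on random instances", {
  cfg <- inference_config(alpha = 0.05)
  set.seed(17)
  for (i in 1:30) {
    n <- 40
    m_cand <- sample(2:6, 1)
    tb <- sample(0:2, n, TRUE)
    cand_bins <- replicate(m_cand, {
      if (runif(1) < 0.4) ifelse(runif(n) < 0.6, tb, sample(0:2, n, TRUE))
      else sample(0:2, n, TRUE)
    }, simplify = FALSE)
    ids <- sprintf("TF%02d", seq_len(m_cand))
    disc <- make_disc(c(list(tb), cand_bins), c("gene", ids))
    got <- infer_parents("gene", ids, disc, cfg)
    want <- oracle_parent_argmax(tb, cand_bins, ids, cfg)
    expect_setequal(got$parents, want$ids)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("independent candidates yield the empty parent set", {
  cfg <- inference_config(alpha = 0.001)
  set.seed(23)
  empty <- vapply(1:40, function(i) {
    n <- 200
    tb <- sample(0:2, n, TRUE)
    cands <- replicate(4, sample(0:2, n, TRUE), simplify = FALSE)
    ids <- paste0("C", 1:4)
    disc <- make_disc(c(list(tb), cands), c("gene", ids))
    length(infer_parents("gene", ids, disc, cfg)$parents) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("an XOR parent pair is recovered past a decoy", {
  cfg <- inference_config(alpha = 0.001)
  set.seed(29)
  hits <- vapply(1:20, function(i) {
    n <- 300
    p1 <- sample(0:1, n, TRUE); p2 <- sample(0:1, n, TRUE)
    tb <- (p1 + p2) %% 2
    decoy <- sample(0:1, n, TRUE)
    disc <- make_disc(list(tb, p1, p2, decoy), c("gene", "P1", "P2", "D"))
    got <- infer_parents("gene", c("P1", "P2", "D"), disc, cfg)
    setequal(got$parents, c("P1", "P2"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("inferred networks respect the prior and tolerate an empty one", {
  d <- generate_dataset(tiny_config(seed = 4))
  m <- knn_impute(filter_missing(d$expression), 10)
  prior <- filter_prior(d$prior, 0.005)
  net <- infer_network(m, prior, inference_config(alpha = 0.001))
  expect_true(all(edge_key(net) %in% edge_key(prior[, c("tf", "target")])))
  expect_false(any(net$tf == net$target))
  expect_gt(edge_f1(edge_key(net), edge_key(d$true_grn)), 0.7)

  empty <- data.frame(tf = character(), target = character(),
                      p = numeric())
  net0 <- infer_network(m, empty, inference_config())
  expect_s3_class(net0, "grn")
  expect_equal(nrow(net0), 0)

  alien <- data.frame(tf = "zzz", target = "yyy", p = 0.001)
  expect_error(infer_network(m, alien, inference_config()), "no gene shared")
})

test_that("expression randomization conserves values and is seed-deterministic", {
  m <- matrix(rnorm(48), 6, dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  r1 <- randomize_expression(m, seed = 5)
  r2 <- randomize_expression(m, seed = 5)
  r3 <- randomize_expression(m, seed = 6)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
  expect_identical(dimnames(r1), dimnames(m))
  expect_equal(sort(as.vector(r1)), sort(as.vector(m)))
})

test_that("z-score edge scoring follows the normal-CDF closed forms", {
  obs <- data.frame(tf = c("A", "B", "C"), target = c("x", "y", "z"),
                    z = c(2.5, 4, 3))
  null <- data.frame(tf = c("A", "B", "C"), target = c("x", "y", "z"),
                     z = c(2.5, -4, 0))
  kept <- panda_edge_scores(obs, null, threshold = 0.8)
  # z_obs = z_null scores 0; (4, -4) ~ 0.99990 kept; (3, 0) ~ 0.49798 dropped
  expect_identical(kept$tf, "B")
  expect_equal(kept$edge_score, (pnorm(4) - pnorm(-4)) * pnorm(4),
               tolerance = 1e-12)

  bad_null <- null; bad_null$target[1] <- "w"
  expect_error(panda_edge_scores(obs, bad_null), "key mismatch")
})

test_that("edge score is monotone in the observed z-score above the null", {
  # monotone wherever Phi(z_obs) >= Phi(z_null)/2; in particular on the
  # whole region z_obs >= z_null, which contains every retainable edge
  z_null <- 0.5
  zs <- seq(0.5, 4, by = 0.25)
  s <- (pnorm(zs) - pnorm(z_null)) * pnorm(zs)
  obs <- data.frame(tf = "A", target = paste0("t", seq_along(zs)), z = zs)
  null <- data.frame(tf = "A", target = paste0("t", seq_along(zs)), z = z_null)
  got <- panda_edge_scores(obs, null, threshold = -Inf)
  ord <- match(paste0("t", seq_along(zs)), got$target)
  expect_equal(got$edge_score[ord], s, tolerance = 1e-12)
  expect_true(all(diff(got$edge_score[ord]) >= 0))
})

test_that("a less stringent alpha never removes a winning parent's edge", {
  set.seed(31)
  n <- 120
  p1 <- sample(0:2, n, TRUE)
  tb <- ifelse(runif(n) < 0.7, p1, sample(0:2, n, TRUE))
  decoy <- sample(0:2, n, TRUE)
  disc <- make_disc(list(tb, p1, decoy), c("gene", "P1", "D"))
  strict <- infer_parents("gene", c("P1", "D"), disc,
                          inference_config(alpha = 0.001))
  loose <- infer_parents("gene", c("P1", "D"), disc,
                         inference_config(alpha = 0.05))
  expect_true(all(strict$parents %in% loose$parents))
  expect_gte(loose$score, strict$score)
})
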