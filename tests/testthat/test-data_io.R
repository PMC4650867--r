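test_that("expression TSV round-trips, including missing entries", {
  m <- expr_mat(1.5, 2, NA,
                3, -0.25, 4,
                genes = c("g1", "g2"), samples = c("s1", "s2", "s3"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, f)
  back <- read_expression(f)
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(back, m)

  # a second round trip is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("missing tokens NA and empty field both become NA", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\tNA\t2", "g2\t\t3"), f)
  m <- read_expression(f)
  expect_true(is.na(m["g1", "s1"]))
  expect_true(is.na(m["g2", "s1"]))
  expect_equal(m[, "s2"], c(g1 = 2, g2 = 3))
})

test_that("malformed expression files fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(read_expression(f), "duplicate gene id: g1")

  writeLines(c("gene\ts1\ts1", "g1\t1\t2"), f)
  expect_error(read_expression(f), "duplicate sample id: s1")

  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3"), f)
  expect_error(read_expression(f), "ragged row at line 3")
})

test_that("filter_missing drops rows then columns at a strict threshold", {
  m <- expr_mat(1, 2, 3, 4,
                NA, NA, NA, 4,
                1, NA, 3, 4,
                genes = c("g1", "g2", "g3"), samples = paste0("s", 1:4))
  expect_identical(filter_missing(m, 0.8), m)  # nothing exceeds 0.8

  # 10-sample gene with 9 missing (0.9 > 0.8) dropped; exactly 8 (0.8) kept
  m10 <- matrix(rnorm(30), nrow = 3,
                dimnames = list(c("ok", "nine", "eight"), paste0("s", 1:10)))
  m10["nine", 1:9] <- NA
  m10["eight", 1:8] <- NA
  out <- filter_missing(m10, 0.8)
  expect_identical(rownames(out), c("ok", "eight"))

  # genes dropped before samples: a column that is mostly missing only
  # because of bad genes survives once those genes are gone
  m2 <- expr_mat(1, 2,
                 NA, 2,
                 NA, 2,
                 NA, 2,
                 genes = paste0("g", 1:4), samples = c("s1", "s2"))
  out2 <- filter_missing(m2, 0.4)
  expect_identical(rownames(out2), "g1")
  expect_identical(colnames(out2), c("s1", "s2"))

  m3 <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(filter_missing(m3, 0.5), "empty matrix")
})

test_that("one-pass filtering bounds every retained gene and sample", {
  set.seed(41)
  for (i in 1:20) {
    m <- matrix(rnorm(120), nrow = 12,
                dimnames = list(paste0("g", 1:12), paste0("s", 1:10)))
    m[sample(length(m), 40)] <- NA
    out <- tryCatch(filter_missing(m, 0.4), error = function(e) NULL)
    if (is.null(out)) next
    # columns are bounded in the final matrix; genes are bounded at the
    # moment they were tested (over the original sample set)
    expect_true(all(colMeans(is.na(out)) <= 0.4))
    expect_true(all(rowMeans(is.na(m[rownames(out), , drop = FALSE])) <= 0.4))
    # filtering never removes observed values from retained entries
    expect_identical(out, m[rownames(out), colnames(out), drop = FALSE])
  }
})

test_that("knn_impute reproduces hand-computed neighbor means", {
  # g3 missing at s2; g1 and g2 are its two nearest genes with values 4, 6
  m <- expr_mat(1, 4, 1,
                1, 6, 1,
                1.1, NA, 1.1,
                9, 9, 9,
                genes = paste0("g", 1:4), samples = paste0("s", 1:3))
  out <- knn_impute(m, k = 2)
  expect_equal(out["g3", "s2"], 5.0)
  expect_equal(out[-3, ], m[-3, ])             # observed entries untouched
  expect_identical(knn_impute(out, k = 2), out) # idempotent once complete
  expect_identical(knn_impute(m[1:2, ], k = 2), m[1:2, ]) # no missing: identity
})

test_that("knn_impute agrees with a brute-force neighbor search", {
  set.seed(7)
  for (i in 1:15) {
    ng <- sample(5:20, 1); ns <- sample(4:10, 1); k <- sample(1:4, 1)
    m <- matrix(rnorm(ng * ns), nrow = ng,
                dimnames = list(paste0("g", 1:ng), paste0("s", 1:ns)))
    m[sample(length(m), round(0.1 * length(m)))] <- NA
    m <- m[rowSums(!is.na(m)) > 0, , drop = FALSE]
    if (nrow(m) < 3) next
    out <- knn_impute(m, k = k)
    expect_false(anyNA(out))
    for (g in seq_len(nrow(m))) for (s in seq_len(ncol(m))) {
      if (!is.na(m[g, s])) next
      d <- rep(Inf, nrow(m))
      for (h in seq_len(nrow(m))) {
        if (h == g) next
        shared <- !is.na(m[g, ]) & !is.na(m[h, ])
        if (any(shared)) d[h] <- sqrt(sum((m[g, shared] - m[h, shared])^2))
      }
      elig <- which(is.finite(d) & !is.na(m[, s]))
      nn <- elig[order(d[elig])][seq_len(min(k, length(elig)))]
      expect_equal(out[g, s], mean(m[nn, s]))
    }
  }
})

test_that("knn_impute rejects a gene with no observed values", {
  m <- expr_mat(1, 2, NA, NA, genes = c("g1", "g2"), samples = c("s1", "s2"))
  expect_error(knn_impute(m, 1), "all entries missing")
})

test_that("sample selection by growth score uses a strict cutoff", {
  g <- expr_mat(-0.2, -0.3,
                -0.1, -0.1,
                0.2, 0.1,
                genes = c("sensitive", "borderline", "resistant"),
                samples = c("rap1", "rap2"))
  expect_identical(select_samples_by_score(g, c("rap1", "rap2"), -0.1),
                   "sensitive")
  expect_error(select_samples_by_score(g, "nope", -0.1), "unknown condition")
})

test_that("a planted 79-strain growth table yields exactly the 30 sensitive strains", {
  d <- generate_dataset(synthetic_config(seed = 3))
  sel <- select_samples_by_score(d$growth, colnames(d$growth), -0.1)
  expect_length(sel, 30)
  expect_setequal(sel, attr(d$growth, "sensitive"))
})

test_that("filter_prior keeps p strictly below alpha", {
  prior <- data.frame(tf = paste0("T", 1:10), target = paste0("g", 1:10),
                      p = c(0.004, 0.005, 0.0049, 0.1, 0.0001,
                            0.0008, 0.9, 0.051, 0.002, 0.0031))
  out <- filter_prior(prior, 0.005)
  expect_equal(nrow(out), 6)                       # 6 of 10 below 0.005
  expect_false("T2" %in% out$tf)                   # p = 0.005 dropped (strict)
  expect_true(all(out$p < 0.005))

  no_p <- prior[, c("tf", "target")]
  expect_error(filter_prior(no_p, 0.005), "no p-value column")
  expect_identical(filter_prior(no_p, NULL), no_p) # alpha absent: unchanged
})

test_that("union_ppi deduplicates unordered pairs across sources", {
  e1 <- data.frame(a = "a", b = "b")
  e2 <- data.frame(a = "b", b = "a")
  expect_equal(nrow(union_ppi(list(e1, e2))), 1)

  # three sources of 5 edges each, 3 of them shared between the first two
  # sources -> 15 - 3 = 12 unique
  shared <- data.frame(a = paste0("s", 1:3), b = paste0("t", 1:3))
  mk <- function(tag, n) data.frame(a = paste0(tag, seq_len(n)),
                                    b = paste0(tag, seq_len(n) + n))
  u <- union_ppi(list(rbind(shared, mk("x", 2)),
                      rbind(shared[, c("b", "a")], mk("y", 2)),
                      mk("z", 5)))
  expect_equal(nrow(u), 12)

  expect_identical(union_ppi(list(e1, e1[0, ])), union_ppi(list(e1)))
  expect_error(union_ppi(list(data.frame(a = c("a", NA), b = c("b", "c")))),
               "malformed pair in source 1 at line 2")
})

test_that("union_ppi size equals the brute-force set cardinality", {
  set.seed(11)
  for (i in 1:10) {
    pools <- replicate(3, {
      n <- sample(5:30, 1)
      data.frame(a = sample(letters[1:8], n, TRUE),
                 b = sample(letters[1:8], n, TRUE))
    }, simplify = FALSE)
    u <- union_ppi(pools)
    norm <- unique(unlist(lapply(pools, function(e) {
      paste(pmin(e$a, e$b), pmax(e$a, e$b))
    })))
    expect_equal(nrow(u), length(norm))
  }
})

test_that("gene sets round-trip through GMT and flat files", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, f)
  expect_identical(read_gene_sets(f), sets)

  flat <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("g1", "g2"), flat)
  got <- read_gene_sets(flat)
  expect_identical(got[[1L]], c("g1", "g2"))
})

test_that("PPI readers accept both 2-column TSV and SIF", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "p1\tp2", "p2\tp1", "p3\tp4"), f)
  expect_equal(nrow(read_ppi(f)), 2)

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("p1 pp p2 p3", "p4 pp p5"), sif)
  got <- read_ppi(sif)
  expect_equal(nrow(got), 3)
  expect_setequal(edge_key(got), c("p1 p2", "p1 p3", "p4 p5"))
})
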