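#' Configuration for regulatory-network inference
#'
#' @param n_bins Bins per gene for discretization (default 3, tertiles).
#' @param max_candidates Maximum candidate regulators per target gene
#'   (default 10); the subset search is exhaustive over these, so 2^10
#'   subsets at most are scored per gene.
#' @param alpha Significance level for the per-parent chi-square penalty
#'   (0.001 for well-sampled datasets, 0.05 for small sample sizes).
#' @param allow_self_loops Whether a gene may be its own regulator
#'   (default FALSE: in a static network a TF trivially has maximal
#'   correlation with itself).
#' @param seed Optional seed recorded in the config for downstream stages.
#' @return List of class `inference_config`.
#' @export
inference_config <- function(n_bins = 3L, max_candidates = 10L, alpha = 0.001,
                             allow_self_loops = FALSE, seed = NULL) {
  assert_scalar_number(max_candidates, "max_candidates", 1)
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_bins = as.integer(n_bins),
                 max_candidates = as.integer(max_candidates),
                 alpha = alpha, allow_self_loops = isTRUE(allow_self_loops),
                 seed = seed),
            class = "inference_config")
}

#' Candidate regulators for one target gene
#'
#' Takes the TFs with a (filtered) prior binding edge to the target,
#' excluding the target itself unless self-loops are allowed, and — when
#' more than `max_candidates` remain — keeps the top `max_candidates` by
#' absolute Pearson correlation with the target (pairwise-complete
#' observations). The returned list is ordered by decreasing |r| with ties
#' broken by identifier order, so the subset search is deterministic.
#'
#' @param target_id Target gene id.
#' @param prior Filtered binding prior (`data.frame(tf, target, ...)`).
#' @param m Expression matrix containing the target row.
#' @param cfg An [inference_config()].
#' @return Character vector of TF ids (possibly empty).
#' @export
select_candidates <- function(target_id, prior, m, cfg = inference_config()) {
  if (!target_id %in% rownames(m)) {
    stop("target absent from expression matrix: ", target_id)
  }
  tfs <- unique(prior$tf[prior$target == target_id])
  if (!cfg$allow_self_loops) tfs <- setdiff(tfs, target_id)
  tfs <- tfs[tfs %in% rownames(m)]
  if (!length(tfs)) return(character(0))
  y <- m[target_id, ]
  r <- vapply(tfs, function(tf) {
    v <- suppressWarnings(stats::cor(m[tf, ], y, use = "pairwise.complete.obs"))
    if (is.na(v)) 0 else abs(v)
  }, numeric(1L))
  ord <- order(-r, tfs)
  tfs[ord][seq_len(min(length(tfs), cfg$max_candidates))]
}

#' Penalized conditional-mutual-information score of an ordered parent set
#'
#' The score of parents P_1..P_m for target T is
#' sum_i \[ 2N * I(T; P_i | P_1..P_{i-1}) - c(alpha, df_i) \]
#' with I in nats, c the upper-tail chi-square critical value and
#' df_i = (r_T - 1)(r_{P_i} - 1) * prod_{k<i} r_{P_k}. Each parent must
#' therefore add more dependence than is expected by chance at level alpha,
#' given the parents already accepted. The empty set scores 0. With all
#' arities equal the total penalty depends only on the set size, making the
#' score order-invariant (the information terms always telescope to the
#' joint information).
#'
#' @param target_bins Integer bin vector of the target.
#' @param parent_bins List of integer bin vectors, one per parent, in
#'   conditioning order.
#' @param cfg An [inference_config()] (only `alpha` is used).
#' @param parent_ids Optional parent identifiers for the report.
#' @return List of class `parent_set_score`: `score`, and a data frame
#'   `terms` with one row per parent (g_stat, df, penalty).
#' @export
score_parent_set <- function(target_bins, parent_bins, cfg = inference_config(),
                             parent_ids = NULL) {
  if (!length(target_bins)) stop("empty target vector")
  if (!is.list(parent_bins)) parent_bins <- list(parent_bins)
  parent_ids <- parent_ids %||% paste0("P", seq_along(parent_bins))
  n <- length(target_bins)
  terms <- vector("list", length(parent_bins))
  score <- 0
  for (i in seq_along(parent_bins)) {
    res <- conditional_mutual_information(
      target_bins, parent_bins[[i]],
      if (i > 1L) parent_bins[seq_len(i - 1L)] else list())
    pen <- chi2_critical(cfg$alpha, res$df)
    score <- score + res$g_stat - pen
    terms[[i]] <- data.frame(tf = parent_ids[i], g_stat = res$g_stat,
                             df = res$df, penalty = pen,
                             stringsAsFactors = FALSE)
  }
  structure(list(score = score,
                 parents = parent_ids,
                 terms = if (length(terms)) do.call(rbind, terms)
                         else data.frame(tf = character(), g_stat = numeric(),
                                         df = integer(), penalty = numeric())),
            class = "parent_set_score")
}

#' Exhaustive parent-set search for one target
#'
#' Scores every subset of the candidate regulators (at most
#' 2^max_candidates) with [score_parent_set()], parents taken in candidate
#' order, and returns the maximal-score subset. Prefix terms are shared
#' across subsets, so each subset costs one additional conditional-MI
#' evaluation. Ties are broken toward smaller subsets, then by sorted
#' parent identifiers; the empty set (score 0) wins any tie at 0, so a
#' parent enters the network only if it strictly beats chance at level
#' alpha.
#'
#' @param target_id Target gene id (row of `disc`).
#' @param candidates Ordered character vector of candidate TF ids
#'   (rows of `disc`), as from [select_candidates()].
#' @param disc A `discretized_matrix`.
#' @param cfg An [inference_config()].
#' @return List of class `parent_set_result`: `target`, `parents`
#'   (in candidate order), `score`, `terms`.
#' @export
infer_parents <- function(target_id, candidates, disc, cfg = inference_config()) {
  stopifnot(inherits(disc, "discretized_matrix"))
  if (length(candidates) > cfg$max_candidates) {
    stop("more candidates than cfg$max_candidates; call select_candidates first")
  }
  tb <- as_codes(disc$bins[target_id, ])
  n <- length(tb$codes)
  m <- length(candidates)
  cand <- lapply(candidates, function(id) as_codes(disc$bins[id, ]))

  n_sub <- 2L^m
  scores <- numeric(n_sub)          # indexed by bitmask + 1
  scores[1L] <- 0
  sizes <- integer(n_sub)
  # DFS over candidates: each inclusion adds one CMI term conditioned on the
  # already-included parents (joint z code carried incrementally).
  walk <- function(i, mask, zc, rz, acc, size) {
    if (i > m) return(invisible())
    # exclude candidate i
    walk(i + 1L, mask, zc, rz, acc, size)
    # include candidate i
    ci <- cand[[i]]
    nats <- cmi_nats(tb$codes, tb$arity, ci$codes, ci$arity, zc, rz)
    df <- (tb$arity - 1L) * (ci$arity - 1L) * rz
    acc2 <- acc + 2 * n * nats - chi2_critical(cfg$alpha, max(df, 1L))
    mask2 <- mask + bitwShiftL(1L, i - 1L)
    scores[mask2 + 1L] <<- acc2
    sizes[mask2 + 1L] <<- size + 1L
    walk(i + 1L, mask2, zc + rz * ci$codes, rz * ci$arity, acc2, size + 1L)
  }
  walk(1L, 0L, integer(n), 1L, 0, 0L)

  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    best <- best[order(sizes[best],
                       vapply(best, function(b) {
                         ids <- candidates[bitwAnd(b - 1L, bitwShiftL(1L, seq_len(m) - 1L)) > 0L]
                         paste(sort(ids), collapse = "\r")
                       }, character(1L)))]
  }
  mask <- best[1L] - 1L
  sel <- if (m) candidates[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L]
         else character(0)
  res <- score_parent_set(tb$codes,
                          lapply(sel, function(id) disc$bins[id, ]),
                          cfg, parent_ids = sel)
  structure(list(target = target_id, parents = sel, score = res$score,
                 terms = res$terms),
            class = "parent_set_result")
}

#' Infer a prior-constrained transcriptional regulatory network
#'
#' Runs the full per-gene procedure: tertile discretization of the
#' expression matrix, candidate selection from the binding prior
#' ([select_candidates()]), then exhaustive penalized parent-set search
#' ([infer_parents()]) for every prior target present in the data. The
#' network's directed edges are the union of selected parent-to-target
#' pairs, so every inferred edge is supported by the prior by construction.
#' Constant (arity-1) genes carry no information and are excluded both as
#' regulators and as targets.
#'
#' @param m Complete (imputed) expression matrix.
#' @param prior Filtered binding prior.
#' @param cfg An [inference_config()].
#' @return Object of class `grn`: `data.frame(tf, target)` with attribute
#'   `fits` holding the per-target `parent_set_result`s.
#' @export
infer_network <- function(m, prior, cfg = inference_config()) {
  disc <- discretize(m, cfg$n_bins)
  informative <- rownames(m)[disc$arity > 1L]
  targets <- intersect(unique(prior$target), informative)
  usable_prior <- prior[prior$tf %in% informative, , drop = FALSE]
  if (!length(targets) || !nrow(usable_prior)) {
    if (!nrow(prior)) {
      return(structure(data.frame(tf = character(), target = character(),
                                  stringsAsFactors = FALSE),
                       class = c("grn", "data.frame")))
    }
    stop("no gene shared between the expression matrix and the prior")
  }
  fits <- lapply(targets, function(tg) {
    cand <- select_candidates(tg, usable_prior, m, cfg)
    if (!length(cand)) return(NULL)
    infer_parents(tg, cand, disc, cfg)
  })
  names(fits) <- targets
  edges <- do.call(rbind, lapply(fits, function(f) {
    if (is.null(f) || !length(f$parents)) return(NULL)
    data.frame(tf = f$parents, target = f$target, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(tf = character(), target = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(edges, class = c("grn", "data.frame"), fits = fits)
}

#' Read / write a directed regulatory network edge list
#'
#' @param path 2-column TSV (tf, target), header optional.
#' @return `data.frame(tf, target)` of class `grn`.
#' @export
read_grn <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("tf", "target")
  structure(df[, 1:2], class = c("grn", "data.frame"))
}

#' @rdname read_grn
#' @param grn Edge data frame.
#' @export
write_grn <- function(grn, path) {
  utils::write.table(as.data.frame(grn)[, c("tf", "target")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Permute gene and sample identities of an expression matrix
#'
#' Builds the randomized control used when post-processing weighted-network
#' scores: the assignment of gene ids to rows and of sample ids to columns
#' are each permuted by an independent seeded draw, so every value survives
#' (same multiset) but all gene/sample structure is destroyed.
#'
#' @param m Expression matrix.
#' @param seed Seed for the two permutation draws.
#' @return Matrix of the same shape and dimnames.
#' @export
randomize_expression <- function(m, seed = NULL) {
  with_seed(seed, {
    rp <- sample.int(nrow(m))
    cp <- sample.int(ncol(m))
    out <- m[rp, cp, drop = FALSE]
    dimnames(out) <- dimnames(m)
    out
  })
}

#' Score weighted-network edges against a randomized control
#'
#' Edge z-scores from a weighted network inference run on the observed data
#' and on a randomized control are each converted to probabilities with the
#' standard normal CDF; the final score of an edge is
#' (Phi(z_obs) - Phi(z_null)) * Phi(z_obs), i.e. the gain in edge
#' probability over the control, re-weighted by the edge's own probability.
#' Edges with score strictly above `threshold` (default 0.8) are retained
#' and form a directed regulatory network.
#'
#' @param obs,null Data frames with columns (tf, target, z); the two key
#'   sets must match exactly.
#' @param threshold Strict lower bound on the retained edge score.
#' @return Data frame of retained edges with columns tf, target, z_obs,
#'   z_null, prob_obs, prob_null, edge_score, of class `grn` for degree
#'   computations.
#' @export
panda_edge_scores <- function(obs, null, threshold = 0.8) {
  names(obs)[1:3] <- c("tf", "target", "z")
  names(null)[1:3] <- c("tf", "target", "z")
  ko <- paste(obs$tf, obs$target, sep = "\r")
  kn <- paste(null$tf, null$target, sep = "\r")
  miss_n <- setdiff(ko, kn); miss_o <- setdiff(kn, ko)
  if (length(miss_n) || length(miss_o)) {
    stop("edge key mismatch between observed and null tables; missing: ",
         paste(sub("\r", " -> ", utils::head(c(miss_n, miss_o), 5L)),
               collapse = ", "))
  }
  z_null <- null$z[match(ko, kn)]
  prob_obs <- stats::pnorm(obs$z)
  prob_null <- stats::pnorm(z_null)
  score <- (prob_obs - prob_null) * prob_obs
  out <- data.frame(tf = obs$tf, target = obs$target,
                    z_obs = obs$z, z_null = z_null,
                    prob_obs = prob_obs, prob_null = prob_null,
                    edge_score = score, stringsAsFactors = FALSE)
  out <- out[score > threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("grn", "data.frame"))
}
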