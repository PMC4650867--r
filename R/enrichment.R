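split_positions <- function(ranked, drivers) {
  if (anyDuplicated(ranked)) stop("ranked list ids must be unique")
  is_pos <- ranked %in% drivers
  if (!any(is_pos) || all(is_pos)) {
    stop("ranked list must contain at least one driver and one non-driver")
  }
  list(pos = which(is_pos), neg = which(!is_pos))
}

#' ROC curve and AUC of a ranked list against a driver set
#'
#' Steps through the list best-first, plotting the true-positive rate
#' (drivers recovered) against the false-positive rate. The AUC equals the
#' Mann-Whitney U statistic normalized by n_pos * n_neg; with tied scores
#' (supplied via `scores`) tied pairs receive half credit.
#'
#' @param ranked Character vector of ids, best first.
#' @param drivers Character vector (or single-set list) of driver ids.
#' @param scores Optional numeric vector parallel to `ranked` (higher =
#'   better); used only to declare ties. Defaults to list positions.
#' @return List with `auc` and `points` (`data.frame(fpr, tpr)`).
#' @export
roc_auc <- function(ranked, drivers, scores = NULL) {
  if (is.list(drivers)) drivers <- drivers[[1L]]
  sp <- split_positions(ranked, drivers)
  goodness <- if (is.null(scores)) -seq_along(ranked) else scores
  rk <- rank(goodness, ties.method = "average")   # higher = better
  n1 <- length(sp$pos); n0 <- length(sp$neg)
  u <- sum(rk[sp$pos]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  is_pos <- seq_along(ranked) %in% sp$pos
  tpr <- c(0, cumsum(is_pos) / n1)
  fpr <- c(0, cumsum(!is_pos) / n0)
  list(auc = auc, points = data.frame(fpr = fpr, tpr = tpr))
}

#' Wilcoxon rank-sum enrichment of drivers toward the top of a list
#'
#' One-sided rank-sum test that drivers occupy better (smaller) positions
#' than non-drivers; exact for small untied samples, normal approximation
#' with continuity and tie correction otherwise (as in
#' [stats::wilcox.test()]).
#'
#' @inheritParams roc_auc
#' @return One-sided p-value.
#' @export
wilcoxon_enrichment <- function(ranked, drivers) {
  if (is.list(drivers)) drivers <- drivers[[1L]]
  sp <- split_positions(ranked, drivers)
  stats::wilcox.test(sp$pos, sp$neg, alternative = "less")$p.value
}

#' Kolmogorov-Smirnov enrichment of drivers toward the top of a list
#'
#' Two-sample KS test comparing the list positions of drivers and
#' non-drivers, one-sided in the direction "drivers shifted toward the
#' top" (their position CDF lies above the non-drivers'). Set
#' `alternative = "two.sided"` to test for any distributional difference
#' (including depletion).
#'
#' @inheritParams roc_auc
#' @param alternative `"enrichment"` (default) or `"two.sided"`.
#' @return p-value.
#' @export
ks_enrichment <- function(ranked, drivers, alternative = c("enrichment", "two.sided")) {
  if (is.list(drivers)) drivers <- drivers[[1L]]
  alternative <- match.arg(alternative)
  sp <- split_positions(ranked, drivers)
  alt <- if (alternative == "enrichment") "greater" else "two.sided"
  suppressWarnings(stats::ks.test(sp$pos, sp$neg, alternative = alt))$p.value
}

# One-sided (enrichment) hypergeometric p and the sample odds ratio ad/bc
# for the 2x2 overlap table of two sets in a finite universe.
overlap_test <- function(n_overlap, n_a, n_b, n_universe,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- n_overlap
  b <- n_a - a
  c_ <- n_b - a
  d <- n_universe - n_a - c_
  if (min(a, b, c_, d) < 0) stop("inconsistent overlap table")
  p <- if (alternative == "greater") {
    stats::phyper(a - 1, n_b, n_universe - n_b, n_a, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, b, c_, d), 2L), alternative = "two.sided")$p.value
  }
  odds <- if (b * c_ == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c_)
  list(overlap = a, p = p, odds_ratio = odds)
}

#' Fisher exact enrichment of drivers among the top k fraction of a list
#'
#' Cuts the ranked list at the top `floor(k_frac * universe_size)` ids and
#' tests the 2x2 overlap of that top set with the driver set by a one-sided
#' (enrichment) Fisher exact test; reports the overlap, the hypergeometric
#' p and the sample odds ratio ad/bc (infinite when bc = 0 and ad > 0).
#'
#' @inheritParams roc_auc
#' @param k_frac Fraction of the universe in (0, 1) forming the top set.
#' @param universe_size Size of the TF universe (default: length of the
#'   list).
#' @param size_rule How the fraction becomes a count: `"floor"` (default),
#'   `"round"` or `"ceiling"`.
#' @return List (k, top_size, overlap, p, odds_ratio).
#' @export
fisher_top_k <- function(ranked, drivers, k_frac, universe_size = length(ranked),
                         size_rule = c("floor", "round", "ceiling")) {
  if (is.list(drivers)) drivers <- drivers[[1L]]
  assert_scalar_number(k_frac, "k_frac", 0, 1)
  size_rule <- match.arg(size_rule)
  n_top <- switch(size_rule,
                  floor = floor(k_frac * universe_size),
                  round = round(k_frac * universe_size),
                  ceiling = ceiling(k_frac * universe_size))
  if (n_top < 1) stop("empty top set: k_frac * universe_size < 1")
  top <- ranked[seq_len(min(n_top, length(ranked)))]
  drivers_in <- intersect(drivers, ranked)
  res <- overlap_test(length(intersect(top, drivers_in)),
                      length(top), length(drivers_in), universe_size)
  c(list(k = k_frac, top_size = length(top)), res)
}

#' Fisher exact test for the overlap of two explicit sets
#'
#' Same 2x2 construction as [fisher_top_k()] but on two given sets, e.g.
#' enriched TFs versus driver TFs in a universe of all tested TFs.
#'
#' @param set_a,set_b Character vectors of ids.
#' @param universe_size Size of the universe both sets are drawn from.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return List (overlap, p, odds_ratio).
#' @export
fisher_overlap <- function(set_a, set_b, universe_size,
                           alternative = c("greater", "two.sided")) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  overlap_test(length(intersect(set_a, set_b)), length(set_a),
               length(set_b), universe_size, match.arg(alternative))
}

#' Per-cluster TF-target enrichment with Benjamini-Hochberg adjustment
#'
#' For each expression cluster and each TF in the prior, tests whether the
#' TF's prior targets are over-represented in the cluster (one-sided Fisher
#' exact on the gene universe), then adjusts the TF p-value vector within
#' each cluster by the Benjamini-Hochberg step-up procedure. A TF is called
#' enriched in a cluster at `p_bh < 0.05` by convention.
#'
#' @param clusters Named list of character vectors (gene clusters).
#' @param prior Binding prior (`data.frame(tf, target, ...)`), already
#'   filtered.
#' @param universe Gene universe (default: union of cluster members and
#'   prior targets).
#' @return Data frame (cluster, tf, overlap, p, p_bh).
#' @export
tf_cluster_enrichment <- function(clusters, prior, universe = NULL) {
  universe <- universe %||% union(unlist(clusters, use.names = FALSE),
                                  unique(prior$target))
  tf_targets <- split(prior$target, prior$tf)
  tf_targets <- lapply(tf_targets, function(t) intersect(unique(t), universe))
  out <- lapply(names(clusters), function(cl) {
    members <- intersect(unique(clusters[[cl]]), universe)
    if (!length(members)) {
      warning("empty cluster skipped: ", cl)
      return(NULL)
    }
    p <- vapply(tf_targets, function(tg) {
      overlap_test(length(intersect(tg, members)), length(tg),
                   length(members), length(universe))$p
    }, numeric(1L))
    ov <- vapply(tf_targets, function(tg) length(intersect(tg, members)),
                 integer(1L))
    data.frame(cluster = cl, tf = names(tf_targets), overlap = ov,
               p = p, p_bh = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Full enrichment report for a ranked TF list
#'
#' Bundles the global measures (AUC, one-sided Wilcoxon and KS p-values)
#' with top-k Fisher overlap tests at the requested fractions.
#'
#' @inheritParams roc_auc
#' @param top_k Numeric vector of top fractions (default 0.1, 0.2, 0.3).
#' @return List of class `enrichment_report`: `auc`, `p_wilcoxon`, `p_ks`,
#'   `top_k` (data frame), `universe_size`, `n_drivers`.
#' @export
enrichment_report <- function(ranked, drivers, top_k = c(0.1, 0.2, 0.3)) {
  if (is.list(drivers)) drivers <- drivers[[1L]]
  tk <- do.call(rbind, lapply(top_k, function(k) {
    r <- fisher_top_k(ranked, drivers, k)
    data.frame(k = k, top_size = r$top_size, overlap = r$overlap,
               p_fisher = r$p, odds_ratio = r$odds_ratio)
  }))
  structure(list(auc = roc_auc(ranked, drivers)$auc,
                 p_wilcoxon = wilcoxon_enrichment(ranked, drivers),
                 p_ks = ks_enrichment(ranked, drivers),
                 top_k = tk,
                 universe_size = length(ranked),
                 n_drivers = length(intersect(drivers, ranked))),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("enrichment: AUC = %.3f, Wilcoxon p = %.3g, KS p = %.3g (%d drivers / %d TFs)\n",
              x$auc, x$p_wilcoxon, x$p_ks, x$n_drivers, x$universe_size))
  print(x$top_k, row.names = FALSE)
  invisible(x)
}
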