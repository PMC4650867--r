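#' Node degree as the number of unique neighbors
#'
#' Degree of a node is the number of distinct neighboring nodes over both
#' outgoing and incoming edges — direction is ignored, duplicate edges
#' count once, and self-loops contribute nothing. Works identically for a
#' directed regulatory network (`tf`, `target` columns) and an undirected
#' interaction network (any two-column edge table).
#'
#' @param network Two-column edge data frame (extra columns ignored).
#' @param nodes Nodes to report (default: every endpoint in the network).
#'   Nodes absent from the network get degree 0.
#' @return Named integer vector of degrees.
#' @export
network_degree <- function(network, nodes = NULL) {
  e <- as.data.frame(network)
  a <- as.character(e[[1L]]); b <- as.character(e[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  pairs <- unique(data.frame(a = c(a, b), b = c(b, a),
                             stringsAsFactors = FALSE))
  nodes <- nodes %||% sort(unique(c(a, b)))
  deg <- table(factor(pairs$a, levels = nodes))
  stats::setNames(as.integer(deg), nodes)
}

#' Rank TFs by degree, with a seeded random bottom block
#'
#' TFs with positive degree are ranked in descending degree order
#' (rank 1 = highest degree), tied degrees receiving the average of the
#' positions they cover. TFs absent from the network (degree 0) carry no
#' information, so they are placed at the bottom of the list in a seeded
#' uniformly random order, each receiving its integer position as rank.
#'
#' @param degrees Named degree vector as from [network_degree()].
#' @param universe TF ids to rank; ids missing from `degrees` get degree 0.
#' @param seed Seed for the bottom-block shuffle.
#' @return Data frame (id, degree, rank, source) where `source` is
#'   `"degree"` or `"random-bottom"`; attribute `seed` records the seed.
#' @export
rank_degrees <- function(degrees, universe, seed = NULL) {
  if (!length(universe)) stop("universe must be non-empty")
  if (anyDuplicated(universe)) stop("universe ids must be unique")
  d <- stats::setNames(rep(0L, length(universe)), universe)
  common <- intersect(universe, names(degrees))
  d[common] <- degrees[common]
  pos <- d > 0L
  rk <- numeric(length(universe))
  rk[pos] <- rank(-d[pos], ties.method = "average")
  n_pos <- sum(pos)
  if (any(!pos)) {
    zero_idx <- which(!pos)
    bottom <- with_seed(seed, zero_idx[sample.int(length(zero_idx))])
    rk[bottom] <- n_pos + seq_along(bottom)
  }
  structure(
    data.frame(id = universe, degree = as.integer(d), rank = rk,
               source = ifelse(pos, "degree", "random-bottom"),
               stringsAsFactors = FALSE, row.names = NULL),
    seed = seed)
}

#' Rank arbitrary per-TF scores (no random bottom block)
#'
#' Average-tie ranking of a named score vector over a universe, for rank
#' sources that are not network degrees (e.g. differential-expression
#' p-values). Rank 1 is the best score.
#'
#' @param scores Named numeric vector.
#' @param universe Ids to rank; must all be present in `scores`.
#' @param decreasing If TRUE (default) larger scores rank better; use
#'   FALSE for p-values.
#' @return Data frame (id, rank, source = "score").
#' @export
rank_scores <- function(scores, universe, decreasing = TRUE) {
  missing <- setdiff(universe, names(scores))
  if (length(missing)) stop("no score for id: ", missing[1L])
  s <- scores[universe]
  rk <- rank(if (decreasing) -s else s, ties.method = "average")
  data.frame(id = universe, rank = as.numeric(rk), source = "score",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fuse two rank tables into a combined score
#'
#' The combined score of a TF is the average of its two ranks,
#' S = (R_1 + R_2) / 2; for degree ranks these are the transcriptional-
#' network rank R_T and the protein-interaction rank R_P. Smaller S means
#' higher priority. The output is sorted ascending by S with ties broken
#' by identifier.
#'
#' @param r1,r2 Rank tables (data frames with `id` and `rank`) covering the
#'   universe, as from [rank_degrees()] or [rank_scores()].
#' @param universe TF ids to score (default: ids of `r1`).
#' @return Data frame (id, R1, R2, S, rank) sorted by S.
#' @export
combine_ranks <- function(r1, r2, universe = r1$id) {
  m1 <- setdiff(universe, r1$id); m2 <- setdiff(universe, r2$id)
  if (length(m1) || length(m2)) {
    stop("rank table missing TF: ", c(m1, m2)[1L])
  }
  a <- r1$rank[match(universe, r1$id)]
  b <- r2$rank[match(universe, r2$id)]
  s <- (a + b) / 2
  out <- data.frame(id = universe, R1 = a, R2 = b, S = s,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$S, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Combined network score from two degree rank tables
#'
#' Convenience wrapper for the canonical fusion of the transcriptional-
#' network degree rank R_T with the protein-interaction degree rank R_P:
#' S = (R_T + R_P)/2. Identical contract to [combine_ranks()]; the output
#' columns are named R_T, R_P, S.
#'
#' @param rt Rank table for the transcriptional network.
#' @param rp Rank table for the protein-interaction network.
#' @param universe TF ids to score.
#' @return Data frame (id, R_T, R_P, S, rank) sorted ascending by S.
#' @export
combined_score <- function(rt, rp, universe = rt$id) {
  out <- combine_ranks(rt, rp, universe)
  names(out)[names(out) == "R1"] <- "R_T"
  names(out)[names(out) == "R2"] <- "R_P"
  out
}

#' Two-group differential expression (Welch t)
#'
#' Per-gene Welch (unequal-variance) t statistic and two-sided p-value
#' between two disjoint sample groups; genes are conventionally ranked by
#' ascending p. A deliberately plain baseline ranking to compare against
#' network-degree rankings.
#'
#' @param m Complete expression matrix.
#' @param group_a,group_b Disjoint sample id vectors, each of size >= 2.
#' @return Data frame (id, statistic, p_value) in input gene order.
#' @export
diff_expression <- function(m, group_a, group_b) {
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) stop("unknown sample id: ", missing[1L])
  xa <- m[, group_a, drop = FALSE]
  xb <- m[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  se2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  zero <- se2 == 0
  t_stat[zero] <- 0
  p[zero] <- 1
  data.frame(id = rownames(m), statistic = t_stat, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}
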