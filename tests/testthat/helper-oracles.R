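# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive summation / enumeration so they share no code path
# with the implementation they check.

expr_mat <- function(..., genes, samples) {
  m <- matrix(c(...), nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  m
}

# a small but non-trivial generator config used by unit tests (the default
# config is exercised by the acceptance suite)
tiny_config <- function(seed = 1L) {
  synthetic_config(n_tfs = 10L, n_targets = 60L, n_samples = 45L,
                   n_drivers = 3L, targets_per_driver = 6L,
                   targets_per_nondriver = 3L,
                   n_hub_tfs = 2L, targets_per_hub = 9L,
                   ppi_n_proteins = 120L, seed = seed)
}

# entropy of a discrete vector, nats
oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

# naive plug-in MI in nats by double summation over observed cells
oracle_mi <- function(x, y) {
  n <- length(x)
  s <- 0
  for (vx in unique(x)) for (vy in unique(y)) {
    pxy <- sum(x == vx & y == vy) / n
    if (pxy > 0) s <- s + pxy * log(pxy / ((sum(x == vx) / n) * (sum(y == vy) / n)))
  }
  s
}

# naive plug-in conditional MI in nats by triple summation
oracle_cmi <- function(x, y, z) {
  n <- length(x)
  s <- 0
  for (vz in unique(z)) {
    sel <- z == vz
    pz <- sum(sel) / n
    for (vx in unique(x)) for (vy in unique(y)) {
      pxyz <- sum(sel & x == vx & y == vy) / n
      if (pxyz > 0) {
        pxz <- sum(sel & x == vx) / n
        pyz <- sum(sel & y == vy) / n
        s <- s + pxyz * log(pxyz * pz / (pxz * pyz))
      }
    }
  }
  s
}

# exhaustive parent-set argmax through score_parent_set (the public scoring
# contract), with the package's tie-breaks: max score, then smaller subset,
# then lexicographic sorted ids
oracle_parent_argmax <- function(target_bins, cand_bins, cand_ids, cfg) {
  m <- length(cand_ids)
  best <- list(score = 0, ids = character(0), size = 0L, key = "")
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
    sc <- if (!length(sel)) 0 else {
      score_parent_set(target_bins, cand_bins[sel], cfg,
                       parent_ids = cand_ids[sel])$score
    }
    key <- paste(sort(cand_ids[sel]), collapse = "|")
    better <- sc > best$score ||
      (sc == best$score && (length(sel) < best$size ||
                            (length(sel) == best$size && key < best$key)))
    if (mask == 0L || better) {
      best <- list(score = sc, ids = cand_ids[sel], size = length(sel), key = key)
    }
  }
  best
}

# degree by explicit adjacency sets
oracle_degree <- function(edges, nodes) {
  vapply(nodes, function(v) {
    nb <- unique(c(edges[[2L]][edges[[1L]] == v], edges[[1L]][edges[[2L]] == v]))
    length(setdiff(nb, v))
  }, integer(1L))
}

# BH step-up by direct arithmetic
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

edge_key <- function(df) paste(df[[1L]], df[[2L]])

edge_f1 <- function(found, truth) {
  tp <- length(intersect(found, truth))
  2 * tp / (length(found) + length(truth))
}
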