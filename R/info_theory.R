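#' Quantile-discretize an expression matrix
#'
#' Each gene is binned independently: thresholds are placed at the
#' j/n_bins empirical quantiles (j = 1..n_bins-1) of the gene's values, and
#' a value's bin is the number of thresholds strictly below it. Ties
#' therefore fall into the lower bin. Occupied bins are relabeled to
#' consecutive integers 0..arity-1, so a gene's arity is the number of
#' expression levels it actually realizes; constant genes get arity 1.
#'
#' @param m Numeric matrix with no missing entries.
#' @param n_bins Number of bins per gene (default 3, i.e. tertiles).
#' @return An object of class `discretized_matrix`: list with integer matrix
#'   `bins` (same dimnames as `m`) and integer vector `arity` per gene.
#' @export
discretize <- function(m, n_bins = 3L) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("discretize requires a complete matrix; impute first")
  assert_scalar_number(n_bins, "n_bins", 2)
  if (ncol(m) < n_bins) {
    stop("fewer samples (", ncol(m), ") than bins (", n_bins, ")")
  }
  probs <- seq_len(n_bins - 1L) / n_bins
  bins <- t(apply(m, 1L, function(x) {
    thr <- stats::quantile(x, probs, names = FALSE, type = 7)
    b <- vapply(x, function(v) sum(thr < v), integer(1L))
    # relabel occupied bins to 0..arity-1
    match(b, sort(unique(b))) - 1L
  }))
  dimnames(bins) <- dimnames(m)
  structure(
    list(bins = bins, arity = apply(bins, 1L, function(b) length(unique(b))),
         n_bins = as.integer(n_bins)),
    class = "discretized_matrix")
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat("discretized_matrix: ", nrow(x$bins), " genes x ", ncol(x$bins),
      " samples, ", x$n_bins, " bins (", sum(x$arity == 1L),
      " constant genes)\n", sep = "")
  invisible(x)
}

# Number of observed levels of an integer bin vector.
observed_arity <- function(x) length(unique(x))

# Plug-in (conditional) mutual information from integer code vectors.
# x, y in 0..rx-1 / 0..ry-1, z an integer stratum code in 0..rz-1 (0 when
# unconditioned). Returns I in nats. The 0*log(0) = 0 convention applies.
cmi_nats <- function(x, rx, y, ry, z = integer(0), rz = 1L) {
  n <- length(x)
  if (length(z) == 0L) z <- integer(n)
  idx <- x + rx * (y + ry * z) + 1L
  n_xyz <- tabulate(idx, nbins = rx * ry * rz)
  n_xz <- tabulate(x + rx * z + 1L, nbins = rx * rz)
  n_yz <- tabulate(y + ry * z + 1L, nbins = ry * rz)
  n_z <- tabulate(z + 1L, nbins = rz)
  pos <- n_xyz > 0L
  if (!any(pos)) return(0)
  cell <- which(pos) - 1L
  cx <- cell %% rx
  cy <- (cell %/% rx) %% ry
  cz <- cell %/% (rx * ry)
  s <- sum(n_xyz[pos] * log((n_xyz[pos] * n_z[cz + 1L]) /
                              (n_xz[cx + rx * cz + 1L] * n_yz[cy + ry * cz + 1L])))
  max(s / n, 0)
}

# Recode an arbitrary discrete vector to integer codes 0..arity-1.
as_codes <- function(x) {
  u <- sort(unique(x))
  list(codes = match(x, u) - 1L, arity = length(u))
}

mi_result <- function(nats, n, df) {
  df <- max(as.integer(round(df)), 1L)
  g <- 2 * n * nats
  structure(
    list(mi_bits = nats / log(2), mi_nats = nats, g_stat = g, df = df,
         n = n, p_value = stats::pchisq(g, df, lower.tail = FALSE)),
    class = "mi_test")
}

#' @export
print.mi_test <- function(x, ...) {
  cat(sprintf("MI = %.4f bits, G = %.3f on df = %d, p = %.3g (N = %d)\n",
              x$mi_bits, x$g_stat, x$df, x$p_value, x$n))
  invisible(x)
}

#' Mutual information between two discretized variables
#'
#' Plug-in estimate I(X;Y) = sum p(x,y) log(p(x,y)/(p(x)p(y))) over the
#' joint empirical distribution, with the G test of independence:
#' G = 2N * I (in nats) referred to a chi-square distribution with
#' (r_x - 1)(r_y - 1) degrees of freedom.
#'
#' @param x,y Equal-length vectors of discrete values (bin labels).
#' @return An `mi_test` list: `mi_bits`, `mi_nats`, `g_stat`, `df`,
#'   `p_value`, `n`.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  if (!length(x)) stop("empty vectors")
  cx <- as_codes(x); cy <- as_codes(y)
  nats <- cmi_nats(cx$codes, cx$arity, cy$codes, cy$arity)
  mi_result(nats, length(x), (cx$arity - 1L) * (cy$arity - 1L))
}

#' Conditional mutual information I(X;Y|Z)
#'
#' Z is the joint (Cartesian-product) variable of the vectors in `z`; with
#' empty `z` this reduces to [mutual_information()]. The G statistic
#' 2N * I is referred to chi-square with
#' (r_x - 1)(r_y - 1) * prod(r_z) degrees of freedom, the classical df for a
#' conditional independence test stratified on Z.
#'
#' @param x,y Equal-length discrete vectors.
#' @param z List of equal-length discrete vectors (possibly empty).
#' @return An `mi_test` list.
#' @export
conditional_mutual_information <- function(x, y, z = list()) {
  if (!is.list(z)) z <- list(z)
  if (!length(z)) return(mutual_information(x, y))
  n <- length(x)
  if (length(y) != n || any(lengths(z) != n)) {
    stop("length mismatch among x, y, z")
  }
  cx <- as_codes(x); cy <- as_codes(y)
  zc <- integer(n); rz <- 1L; df_z <- 1
  for (v in z) {
    cv <- as_codes(v)
    zc <- zc + rz * cv$codes
    rz <- rz * cv$arity
    df_z <- df_z * cv$arity
  }
  nats <- cmi_nats(cx$codes, cx$arity, cy$codes, cy$arity, zc, rz)
  mi_result(nats, n, (cx$arity - 1L) * (cy$arity - 1L) * df_z)
}

#' Upper-tail chi-square critical value
#'
#' The value c with P(Chisq(df) > c) = alpha; used as the per-parent
#' complexity penalty in the parent-set score and for significance cutoffs.
#'
#' @param alpha Upper-tail probability in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @export
chi2_critical <- function(alpha, df) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(df) || any(df < 1)) stop("df must be >= 1")
  stats::qchisq(alpha, df, lower.tail = FALSE)
}

#' Permutation p-value for a (conditional) mutual-information G statistic
#'
#' Seeded alternative to the asymptotic chi-square reference: permutes `y`
#' within strata of Z and reports the fraction of permuted G statistics at
#' least as large as the observed one (add-one estimator).
#'
#' @param x,y,z As in [conditional_mutual_information()].
#' @param B Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return An `mi_test` list with `p_value` replaced by the permutation
#'   p-value and an added `B` field.
#' @export
permutation_mi_test <- function(x, y, z = list(), B = 1000L, seed = NULL) {
  obs <- conditional_mutual_information(x, y, z)
  if (!is.list(z)) z <- list(z)
  n <- length(x)
  strata <- if (length(z)) {
    interaction(as.data.frame(z), drop = TRUE)
  } else factor(rep(1L, n))
  ge <- with_seed(seed, {
    sum(vapply(seq_len(B), function(b) {
      yp <- y
      for (lev in levels(strata)) {
        i <- which(strata == lev)
        yp[i] <- y[i[sample.int(length(i))]]
      }
      conditional_mutual_information(x, yp, z)$g_stat >= obs$g_stat
    }, logical(1L)))
  })
  obs$p_value <- (ge + 1) / (B + 1)
  obs$B <- B
  obs
}
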