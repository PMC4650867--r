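#' Read a gene-by-sample expression matrix from TSV
#'
#' Expression data are stored as a numeric matrix with genes as rows and
#' samples as columns; `NA` entries mark missing measurements. The file must
#' have one header row of sample identifiers and a first column of gene
#' identifiers. Identifiers are opaque, case-sensitive strings.
#'
#' @param path Path to a tab-separated file.
#' @param missing_tokens Character vector of field values treated as missing
#'   (default `"NA"` and the empty field).
#' @return A numeric matrix with `rownames` (genes) and `colnames` (samples).
#' @export
read_expression <- function(path, missing_tokens = c("NA", "")) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file needs a header and >= 1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading corner label for the gene column
  ncol_data <- length(fields[[2L]]) - 1L
  sample_ids <- if (length(header) == ncol_data) header else header[-1L]
  if (length(sample_ids) != ncol_data) {
    stop("header has ", length(sample_ids), " sample ids but data rows have ",
         ncol_data, " value columns")
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample id: ", dup[1L])

  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != ncol_data + 1L)
  if (length(bad)) {
    stop("ragged row at line ", bad[1L] + 1L, ": expected ",
         ncol_data + 1L, " fields, found ", widths[bad[1L]])
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1L])

  vals <- vapply(body, function(f) {
    v <- f[-1L]
    v[v %in% missing_tokens] <- NA_character_
    as.numeric(v)
  }, numeric(ncol_data))
  m <- if (ncol_data == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: missing entries are emitted as `NA`.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes and samples with too many missing values
#'
#' Removes first the genes (rows), then the samples (columns), whose fraction
#' of missing entries strictly exceeds `max_frac`. One pass each, genes
#' before samples; row and column order are preserved. Because filtering is
#' single-pass, each gene is bounded with respect to the original sample
#' set; at the default `max_frac = 0.8` the retained genes in practice also
#' satisfy the bound over the retained samples.
#'
#' @param m Expression matrix (may contain `NA`).
#' @param max_frac Maximum tolerated missing fraction (default 0.8).
#' @return The filtered matrix.
#' @export
filter_missing <- function(m, max_frac = 0.8) {
  assert_scalar_number(max_frac, "max_frac", 0, 1)
  keep_genes <- rowMeans(is.na(m)) <= max_frac
  if (!any(keep_genes)) stop("empty matrix: all genes exceed the missing-value bound")
  m <- m[keep_genes, , drop = FALSE]
  keep_samples <- colMeans(is.na(m)) <= max_frac
  if (!any(keep_samples)) stop("empty matrix: all samples exceed the missing-value bound")
  m[, keep_samples, drop = FALSE]
}

#' Impute missing expression values by k-nearest neighbors
#'
#' Each missing entry is replaced by the mean value, at that sample, of the
#' `k` nearest genes. Distance between two genes is the Euclidean distance
#' over the samples where both are observed; genes with no co-observed
#' samples are not eligible neighbors. Only genes observed at the sample
#' being imputed are candidates. Distance ties are broken by input gene
#' order. Observed entries are never modified.
#'
#' @param m Expression matrix after [filter_missing()].
#' @param k Number of neighbors (default 10).
#' @return Matrix with no missing entries.
#' @export
knn_impute <- function(m, k = 10L) {
  stopifnot(is.matrix(m))
  assert_scalar_number(k, "k", 1)
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    stop("gene with all entries missing (should have been filtered): ",
         rownames(m)[all_missing][1L])
  }
  if (!anyNA(m)) return(m)
  out <- m
  need <- which(rowSums(is.na(m)) > 0L)
  for (g in need) {
    x <- m[g, ]
    obs_x <- !is.na(x)
    # Euclidean distance over co-observed samples, per candidate neighbor
    d <- apply(m, 1L, function(y) {
      shared <- obs_x & !is.na(y)
      if (!any(shared)) return(Inf)
      sqrt(sum((x[shared] - y[shared])^2))
    })
    d[g] <- Inf
    for (s in which(is.na(x))) {
      eligible <- which(is.finite(d) & !is.na(m[, s]))
      if (!length(eligible)) {
        stop("no eligible neighbor to impute gene ", rownames(m)[g],
             " at sample ", colnames(m)[s])
      }
      nn <- eligible[order(d[eligible])][seq_len(min(k, length(eligible)))]
      out[g, s] <- mean(m[nn, s])
    }
  }
  out
}

#' Read a strain-by-condition growth-score table
#'
#' @param path TSV with a header of condition ids and a first column of
#'   strain ids.
#' @return Numeric matrix, strains as rows and conditions as columns.
#' @export
read_growth <- function(path) read_expression(path)

#' @rdname read_growth
#' @param g Growth matrix.
#' @export
write_growth <- function(g, path) write_expression(g, path)

#' Select strains by mean growth score under chosen conditions
#'
#' Returns the strains whose mean score over the named conditions is strictly
#' below `cutoff`. Used to restrict expression samples to, e.g., the strains
#' most sensitive to a drug (mean relative growth below -0.1).
#'
#' @param g Growth matrix (strains x conditions).
#' @param conditions Condition ids to average over (default: all).
#' @param cutoff Strict upper bound on the mean score (default -0.1).
#' @return Character vector of selected strain ids, in input order.
#' @export
select_samples_by_score <- function(g, conditions = colnames(g), cutoff = -0.1) {
  unknown <- setdiff(conditions, colnames(g))
  if (length(unknown)) stop("unknown condition: ", unknown[1L])
  score <- rowMeans(g[, conditions, drop = FALSE], na.rm = TRUE)
  rownames(g)[score < cutoff]
}

#' Read / write a TF-to-target binding prior
#'
#' The prior is a data frame with character columns `tf` and `target` and an
#' optional numeric `p` column of binding-site p-values. (tf, target) pairs
#' must be unique.
#'
#' @param path TSV with 2 or 3 columns (tf, target, p); a header row is
#'   detected by a non-numeric third field named anything.
#' @return `data.frame(tf, target[, p])`.
#' @export
read_prior <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("prior file needs at least 2 columns (tf, target)")
  names(df)[1:2] <- c("tf", "target")
  if (ncol(df) >= 3L) names(df)[3L] <- "p"
  df <- df[, intersect(c("tf", "target", "p"), names(df)), drop = FALSE]
  validate_prior(df)
  df
}

#' @rdname read_prior
#' @param prior Prior data frame.
#' @export
write_prior <- function(prior, path) {
  utils::write.table(prior, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_prior <- function(prior) {
  key <- paste(prior$tf, prior$target, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) stop("duplicate (tf, target) pair in prior: ",
                        sub("\r", " -> ", dup[1L]))
  if ("p" %in% names(prior)) {
    bad <- !is.na(prior$p) & (prior$p < 0 | prior$p > 1)
    if (any(bad)) stop("prior p-values outside [0, 1]")
  }
  invisible(prior)
}

#' Filter a binding prior at a p-value cutoff
#'
#' Keeps records whose binding p-value is strictly below `alpha`
#' (default 0.005, the usual binding-site stringency). With `alpha = NULL`
#' the prior is returned unchanged, which is the only way to use a prior
#' that carries no p-value column.
#'
#' @param prior Prior data frame from [read_prior()].
#' @param alpha Strict upper bound on the p-value, or NULL to skip.
#' @return Filtered prior.
#' @export
filter_prior <- function(prior, alpha = 0.005) {
  if (is.null(alpha)) return(prior)
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (!"p" %in% names(prior)) {
    stop("alpha given but the prior has no p-value column")
  }
  prior[!is.na(prior$p) & prior$p < alpha, , drop = FALSE]
}

#' Combine protein-interaction edge lists into one undirected network
#'
#' Edges are unordered pairs: (a, b) and (b, a) are the same edge and each
#' unique pair is kept once. Self-pairs are retained in the edge table but
#' contribute nothing to degree (see [network_degree()]).
#'
#' @param edge_lists A list of 2-column data frames / matrices of node id
#'   pairs (e.g. Y2H, co-complex, literature interactions), or a single one.
#' @return `data.frame(a, b)` with `a <= b` canonical order.
#' @export
union_ppi <- function(edge_lists) {
  if (is.data.frame(edge_lists) || is.matrix(edge_lists)) {
    edge_lists <- list(edge_lists)
  }
  parts <- lapply(seq_along(edge_lists), function(i) {
    e <- edge_lists[[i]]
    if (is.matrix(e)) e <- as.data.frame(e, stringsAsFactors = FALSE)
    if (nrow(e) && ncol(e) < 2L) {
      stop("malformed pair in source ", i, ": fewer than 2 columns")
    }
    if (!nrow(e)) return(data.frame(a = character(), b = character()))
    a <- as.character(e[[1L]]); b <- as.character(e[[2L]])
    bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
    if (length(bad)) {
      stop("malformed pair in source ", i, " at line ", bad[1L])
    }
    data.frame(a = pmin(a, b), b = pmax(a, b), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  all[!duplicated(paste(all$a, all$b, sep = "\r")), , drop = FALSE]
}

#' Read / write protein-interaction edge lists
#'
#' Accepts a 2-column TSV (with or without header) or SIF
#' (`node relation node ...`) format; returns the deduplicated undirected
#' edge table of [union_ppi()].
#'
#' @param path Input file.
#' @return `data.frame(a, b)`.
#' @export
read_ppi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[\t ]+")
  n <- lengths(fields)
  if (any(n < 2L)) stop("malformed pair in ", path, " at line ", which(n < 2L)[1L])
  is_sif <- all(n >= 3L) && !all(n == 2L)
  pairs <- if (is_sif) {
    # SIF: source, relation, one or more targets
    do.call(rbind, lapply(fields, function(f) {
      cbind(f[1L], f[-(1:2)])
    }))
  } else {
    do.call(rbind, lapply(fields, function(f) f[1:2]))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs) <- c("a", "b")
  # drop a header line if present
  if (nrow(pairs) && identical(tolower(pairs$a[1L]), "a")) pairs <- pairs[-1L, ]
  union_ppi(pairs)
}

#' @rdname read_ppi
#' @param ppi Edge data frame.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(ppi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets
#'
#' GMT files (one set per line: name, description, then member ids) become a
#' named list of character vectors; a flat one-id-per-line file becomes a
#' single-set list named after the file.
#'
#' @param path GMT or flat text file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(fields) == 1L)) {
    sets <- list(unique(trimws(lines)))
    names(sets) <- sub("\\.[^.]*$", "", basename(path))
    return(sets)
  }
  if (any(lengths(fields) < 3L)) {
    stop("GMT line ", which(lengths(fields) < 3L)[1L],
         " has fewer than 3 fields (name, description, members)")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  sets
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
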