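#' Configuration for the synthetic benchmark generator
#'
#' Defines a complete ground-truthed study: a planted TF-to-target
#' regulatory layer driving discretizable expression, a scale-free
#' protein-interaction layer in which driver TFs sit in a moderate-degree
#' band, a binding prior containing the true edges plus decoys, and a
#' strain-by-condition growth table with a planted sensitive subset.
#'
#' @param n_tfs Number of transcription factors (default 40).
#' @param n_targets Number of (non-TF) target genes (default 400).
#' @param n_samples Number of expression samples (default 60).
#' @param n_drivers Number of driver TFs (default 8).
#' @param targets_per_driver Regulated targets per driver TF (default 15).
#' @param targets_per_nondriver Average regulated targets per non-driver
#'   TF (default 3); fixes the total non-driver edge budget at
#'   `(n_tfs - n_drivers) * targets_per_nondriver`.
#' @param n_hub_tfs,targets_per_hub A few non-driver "housekeeping hub"
#'   TFs (default 3) receive `targets_per_hub` targets each (default 18,
#'   more than a driver), drawn from the non-driver edge budget; the rest
#'   of the budget is spread evenly over the remaining non-drivers. This
#'   reproduces the structure real regulatory networks show: the
#'   highest-degree regulators are broadly acting housekeeping factors,
#'   while condition drivers sit above the median but below the hubs, so
#'   no single network layer ranks them perfectly.
#' @param prior_false_positive_edges Decoy prior edges per target that pass
#'   the binding p-value cutoff but have no regulatory effect (default 5).
#' @param prior_chaff_per_target Additional prior edges per target with
#'   p-values above the 0.005 cutoff, removed by [filter_prior()]
#'   (default 2).
#' @param ppi_n_proteins Nodes in the protein-interaction layer
#'   (default 800).
#' @param ppi_attachment Edges added per node in the preferential-
#'   attachment construction (default 2).
#' @param driver_ppi_degree_quantile Two-sided quantile band of the PPI
#'   degree distribution into which driver TFs are wired (default
#'   c(0.6, 0.9): above median but below the hubs).
#' @param noise_flip_prob Probability that a target's expression level
#'   ignores its regulators and is drawn uniformly (default 0.2).
#' @param level_means,level_sd Gaussian mixture emitting expression from
#'   the three latent levels (defaults -2, 0, 2 and sd 0.5, well separated
#'   so that tertile binning recovers the latent level).
#' @param missing_frac Fraction of expression entries masked as missing to
#'   exercise the imputation path (default 0.02).
#' @param n_strains,n_sensitive,n_conditions Growth-table shape: strains
#'   total, strains planted below the -0.1 sensitivity cutoff, and
#'   conditions averaged (defaults 79, 30, 7).
#' @param seed Master seed; fans out to independent per-component streams.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tfs = 40L, n_targets = 400L, n_samples = 60L,
                             n_drivers = 8L, targets_per_driver = 15L,
                             targets_per_nondriver = 3L,
                             n_hub_tfs = 3L, targets_per_hub = 18L,
                             prior_false_positive_edges = 5L,
                             prior_chaff_per_target = 2L,
                             ppi_n_proteins = 800L, ppi_attachment = 2L,
                             driver_ppi_degree_quantile = c(0.6, 0.9),
                             noise_flip_prob = 0.2,
                             level_means = c(-2, 0, 2), level_sd = 0.5,
                             missing_frac = 0.02,
                             n_strains = 79L, n_sensitive = 30L,
                             n_conditions = 7L, seed = 1L) {
  cfg <- list(n_tfs = as.integer(n_tfs), n_targets = as.integer(n_targets),
              n_samples = as.integer(n_samples),
              n_drivers = as.integer(n_drivers),
              targets_per_driver = as.integer(targets_per_driver),
              targets_per_nondriver = as.integer(targets_per_nondriver),
              n_hub_tfs = as.integer(n_hub_tfs),
              targets_per_hub = as.integer(targets_per_hub),
              prior_false_positive_edges = as.integer(prior_false_positive_edges),
              prior_chaff_per_target = as.integer(prior_chaff_per_target),
              ppi_n_proteins = as.integer(ppi_n_proteins),
              ppi_attachment = as.integer(ppi_attachment),
              driver_ppi_degree_quantile = driver_ppi_degree_quantile,
              noise_flip_prob = noise_flip_prob,
              level_means = level_means, level_sd = level_sd,
              missing_frac = missing_frac,
              n_strains = as.integer(n_strains),
              n_sensitive = as.integer(n_sensitive),
              n_conditions = as.integer(n_conditions),
              seed = seed)
  counts <- c("n_tfs", "n_targets", "n_samples", "n_drivers",
              "targets_per_driver", "targets_per_nondriver",
              "ppi_n_proteins", "ppi_attachment", "n_strains",
              "n_sensitive", "n_conditions")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop(f, " must be positive")
  }
  if (cfg$n_drivers > cfg$n_tfs) stop("infeasible config: more drivers than TFs")
  if (cfg$n_sensitive > cfg$n_strains) {
    stop("infeasible config: more sensitive strains than strains")
  }
  if (cfg$targets_per_driver > cfg$n_targets ||
      cfg$targets_per_nondriver > cfg$n_targets ||
      cfg$targets_per_hub > cfg$n_targets) {
    stop("infeasible config: more targets per TF than targets")
  }
  n_nondriver <- cfg$n_tfs - cfg$n_drivers
  if (cfg$n_hub_tfs >= n_nondriver) {
    stop("infeasible config: n_hub_tfs must be smaller than the number of non-driver TFs")
  }
  if (cfg$n_hub_tfs * cfg$targets_per_hub >
      n_nondriver * cfg$targets_per_nondriver) {
    stop("infeasible config: hub TFs exceed the non-driver edge budget")
  }
  assert_scalar_number(cfg$noise_flip_prob, "noise_flip_prob", 0, 1)
  assert_scalar_number(cfg$missing_frac, "missing_frac", 0, 1)
  structure(cfg, class = "synthetic_config")
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate a complete ground-truthed synthetic dataset
#'
#' Expression is emitted by a latent discrete mechanism: every TF draws a
#' level in \{0,1,2\} uniformly per sample; every regulated target copies a
#' randomly weighted average of its regulators' levels (thresholded back to
#' three levels) with probability 1 - noise_flip_prob, otherwise a uniform
#' level; levels map to Gaussian-jittered values, so tertile binning
#' approximately recovers the latent levels. The prior contains every true
#' edge (binding p < 0.004) plus per-target decoys passing the 0.005
#' cutoff and chaff above it. The PPI layer is a preferential-attachment
#' graph with driver TFs wired into a moderate-degree band and the other
#' TFs placed uniformly. The growth table plants exactly `n_sensitive`
#' strains with mean score below -0.1.
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `synthetic_dataset` with elements `expression`,
#'   `prior`, `ppi`, `true_grn`, `drivers`, `growth`, `tf_ids`,
#'   `target_ids`, `sample_groups`, `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seeds <- derive_seeds(cfg$seed, 6L)

  tf_ids <- pad_ids("TF", cfg$n_tfs)
  target_ids <- pad_ids("G", cfg$n_targets)
  sample_ids <- pad_ids("S", cfg$n_samples)

  # --- regulatory structure -------------------------------------------------
  grn <- with_seed(seeds[[1L]], {
    drivers <- sort(sample(tf_ids, cfg$n_drivers))
    nondrivers <- setdiff(tf_ids, drivers)
    hubs <- sort(sample(nondrivers, cfg$n_hub_tfs))
    rest <- setdiff(nondrivers, hubs)
    # non-driver edge budget: hubs get targets_per_hub each, the remainder
    # is spread evenly, so the total edge count stays
    # n_drivers*targets_per_driver + (n_tfs-n_drivers)*targets_per_nondriver
    budget <- length(nondrivers) * cfg$targets_per_nondriver -
      cfg$n_hub_tfs * cfg$targets_per_hub
    k_rest <- rep(budget %/% length(rest), length(rest))
    k_rest[seq_len(budget %% length(rest))] <- k_rest[1L] + 1L
    k_all <- stats::setNames(rep(cfg$targets_per_driver, cfg$n_tfs), tf_ids)
    k_all[hubs] <- cfg$targets_per_hub
    k_all[rest] <- k_rest
    edges <- do.call(rbind, lapply(tf_ids, function(tf) {
      k <- k_all[[tf]]
      if (k == 0L) return(NULL)
      data.frame(tf = tf, target = sample(target_ids, k),
                 stringsAsFactors = FALSE)
    }))
    list(drivers = drivers, hubs = hubs, edges = edges)
  })
  regulators <- split(grn$edges$tf, grn$edges$target)

  # --- expression -----------------------------------------------------------
  expression <- with_seed(seeds[[2L]], {
    tf_bins <- matrix(sample.int(3L, cfg$n_tfs * cfg$n_samples, replace = TRUE) - 1L,
                      nrow = cfg$n_tfs, dimnames = list(tf_ids, sample_ids))
    target_bins <- matrix(sample.int(3L, cfg$n_targets * cfg$n_samples,
                                     replace = TRUE) - 1L,
                          nrow = cfg$n_targets,
                          dimnames = list(target_ids, sample_ids))
    for (tg in names(regulators)) {
      regs <- regulators[[tg]]
      w <- stats::runif(length(regs), 0.5, 1)
      w <- w / sum(w)
      comb <- as.vector(w %*% tf_bins[regs, , drop = FALSE])
      planted <- findInterval(comb, c(2 / 3, 4 / 3))
      keep <- stats::runif(cfg$n_samples) >= cfg$noise_flip_prob
      target_bins[tg, keep] <- planted[keep]
    }
    bins <- rbind(tf_bins, target_bins)
    vals <- cfg$level_means[bins + 1L] +
      stats::rnorm(length(bins), 0, cfg$level_sd)
    matrix(vals, nrow = nrow(bins), dimnames = dimnames(bins))
  })

  # --- binding prior: true edges + decoys + chaff ---------------------------
  prior <- with_seed(seeds[[3L]], {
    true_p <- data.frame(tf = grn$edges$tf, target = grn$edges$target,
                         p = stats::runif(nrow(grn$edges), 0, 0.004),
                         stringsAsFactors = FALSE)
    extra <- do.call(rbind, lapply(target_ids, function(tg) {
      used <- grn$edges$tf[grn$edges$target == tg]
      free <- setdiff(tf_ids, used)
      decoy <- sample(free, min(cfg$prior_false_positive_edges, length(free)))
      free2 <- setdiff(free, decoy)
      chaff <- sample(free2, min(cfg$prior_chaff_per_target, length(free2)))
      rbind(
        data.frame(tf = decoy, target = tg,
                   p = stats::runif(length(decoy), 0, 0.0049),
                   stringsAsFactors = FALSE),
        data.frame(tf = chaff, target = tg,
                   p = stats::runif(length(chaff), 0.01, 0.9),
                   stringsAsFactors = FALSE))
    }))
    p <- rbind(true_p, extra)
    rownames(p) <- NULL
    p
  })

  # --- protein-interaction layer --------------------------------------------
  ppi <- with_seed(seeds[[4L]], {
    g <- igraph::sample_pa(cfg$ppi_n_proteins, power = 1,
                           m = cfg$ppi_attachment, directed = FALSE)
    deg <- igraph::degree(g)
    ord <- order(deg, sample.int(length(deg)))   # random ties
    lo <- ceiling(cfg$driver_ppi_degree_quantile[1L] * cfg$ppi_n_proteins)
    hi <- floor(cfg$driver_ppi_degree_quantile[2L] * cfg$ppi_n_proteins)
    band <- ord[lo:hi]
    driver_nodes <- sample(band, cfg$n_drivers)
    rest <- setdiff(seq_len(cfg$ppi_n_proteins), driver_nodes)
    nondriver <- setdiff(tf_ids, grn$drivers)
    other_nodes <- sample(rest, length(nondriver))
    node_names <- pad_ids("P", cfg$ppi_n_proteins)
    node_names[driver_nodes] <- grn$drivers
    node_names[other_nodes] <- nondriver
    e <- igraph::as_edgelist(g)
    union_ppi(data.frame(a = node_names[e[, 1L]], b = node_names[e[, 2L]],
                         stringsAsFactors = FALSE))
  })

  # --- growth table ---------------------------------------------------------
  growth <- with_seed(seeds[[5L]], {
    strain_ids <- pad_ids("strain", cfg$n_strains)
    sens <- sample(strain_ids, cfg$n_sensitive)
    g <- matrix(stats::runif(cfg$n_strains * cfg$n_conditions, -0.05, 0.2),
                nrow = cfg$n_strains,
                dimnames = list(strain_ids, pad_ids("cond", cfg$n_conditions)))
    g[sens, ] <- stats::runif(cfg$n_sensitive * cfg$n_conditions, -0.5, -0.15)
    attr(g, "sensitive") <- sort(sens)
    g
  })

  # --- missingness ----------------------------------------------------------
  expression <- with_seed(seeds[[6L]], {
    n_missing <- round(cfg$missing_frac * length(expression))
    if (n_missing > 0L) {
      idx <- sample(length(expression), n_missing)
      expression[idx] <- NA_real_
      # never leave a gene with < 2 observed values
      starved <- which(rowSums(!is.na(expression)) < 2L)
      for (g in starved) {
        miss <- which(is.na(expression[g, ]))
        restore <- miss[seq_len(2L - sum(!is.na(expression[g, ])))]
        expression[g, restore] <- cfg$level_means[2L]
      }
    }
    expression
  })

  half <- ceiling(cfg$n_samples / 2)
  structure(
    list(expression = expression,
         prior = validate_prior(prior),
         ppi = ppi,
         true_grn = structure(grn$edges, class = c("grn", "data.frame")),
         drivers = list(drivers = grn$drivers),
         hub_tfs = grn$hubs,
         growth = growth,
         tf_ids = tf_ids, target_ids = target_ids,
         sample_groups = list(group_a = sample_ids[seq_len(half)],
                              group_b = sample_ids[-seq_len(half)]),
         config = cfg),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples;", nrow(x$true_grn), "true edges;",
      nrow(x$prior), "prior records;", nrow(x$ppi), "PPI edges;",
      length(x$drivers$drivers), "driver TFs\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory of standard files
#'
#' Emits every input format the pipeline consumes (expression TSV, prior
#' TSV, PPI TSV, true-network TSV, drivers GMT, growth TSV) plus a JSON
#' manifest listing each file with its MD5 content hash and the generating
#' configuration.
#'
#' @param d A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = "expression.tsv", prior = "prior.tsv",
             ppi = "ppi.tsv", true_grn = "true_grn.tsv",
             drivers = "drivers.gmt", growth = "growth.tsv")
  paths[] <- file.path(dir, paths)
  write_expression(d$expression, paths[["expression"]])
  write_prior(d$prior, paths[["prior"]])
  write_ppi(d$ppi, paths[["ppi"]])
  write_grn(d$true_grn, paths[["true_grn"]])
  write_gene_sets(d$drivers, paths[["drivers"]])
  write_growth(d$growth, paths[["growth"]])
  manifest <- list(
    files = lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    config = unclass(d$config),
    tf_ids = d$tf_ids,
    sample_groups = d$sample_groups)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing the standard files.
#' @return List with `expression`, `prior`, `ppi`, `true_grn`, `drivers`,
#'   `growth` (ground-truth fields such as the config come from the
#'   manifest when present).
#' @export
read_dataset <- function(dir) {
  out <- list(expression = read_expression(file.path(dir, "expression.tsv")),
              prior = read_prior(file.path(dir, "prior.tsv")),
              ppi = read_ppi(file.path(dir, "ppi.tsv")),
              true_grn = read_grn(file.path(dir, "true_grn.tsv")),
              drivers = read_gene_sets(file.path(dir, "drivers.gmt")),
              growth = read_growth(file.path(dir, "growth.tsv")))
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    out$tf_ids <- manifest$tf_ids
    out$sample_groups <- manifest$sample_groups
  }
  out
}
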