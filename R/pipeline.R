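#' Configuration for a full pipeline run
#'
#' Inputs may be file paths (the standard TSV/GMT dialects) or the
#' corresponding in-memory objects; paths are resolved at run time.
#'
#' @param expression Expression matrix or TSV path.
#' @param prior Binding prior or TSV path.
#' @param ppi Protein-interaction edge table or TSV/SIF path.
#' @param drivers Driver gene set (character vector, single-set list, or
#'   GMT/flat-file path).
#' @param growth Optional growth table or path; when given together with
#'   `growth_conditions`, samples are restricted to strains scoring below
#'   `growth_cutoff`.
#' @param growth_conditions,growth_cutoff Sample-selection parameters
#'   (defaults: all conditions, -0.1).
#' @param group_a,group_b Sample groups for the differential-expression
#'   baseline (default: first half vs second half of samples).
#' @param inference An [inference_config()].
#' @param prior_alpha Binding p-value cutoff for [filter_prior()]
#'   (default 0.005); NULL skips filtering.
#' @param max_missing Missing-fraction bound for [filter_missing()]
#'   (default 0.8).
#' @param knn_k Neighbors for [knn_impute()] (default 10).
#' @param scoring_seed Seed for the random bottom blocks of the degree
#'   rankings (default 1).
#' @param top_k Top fractions for the Fisher overlap tests
#'   (default 0.1, 0.2, 0.3).
#' @param outdir Output directory for stage artifacts, or NULL to skip
#'   writing.
#' @return List of class `run_config`.
#' @export
run_config <- function(expression, prior, ppi, drivers, growth = NULL,
                       growth_conditions = NULL, growth_cutoff = -0.1,
                       group_a = NULL, group_b = NULL,
                       inference = inference_config(), prior_alpha = 0.005,
                       max_missing = 0.8, knn_k = 10L, scoring_seed = 1L,
                       top_k = c(0.1, 0.2, 0.3), outdir = NULL) {
  structure(list(expression = expression, prior = prior, ppi = ppi,
                 drivers = drivers, growth = growth,
                 growth_conditions = growth_conditions,
                 growth_cutoff = growth_cutoff,
                 group_a = group_a, group_b = group_b,
                 inference = inference, prior_alpha = prior_alpha,
                 max_missing = max_missing, knn_k = knn_k,
                 scoring_seed = scoring_seed, top_k = top_k,
                 outdir = outdir),
            class = "run_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input file does not exist: ", x)
    reader(x)
  } else x
}

run_stage <- function(name, timings_env, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  timings_env$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  res
}

#' Run the full prioritization pipeline
#'
#' Executes preprocess -> network inference -> degree scoring -> rank
#' fusion -> enrichment. Five rankings of the TF universe are evaluated
#' against the driver set: transcriptional-network degree, protein-
#' interaction degree, the combined score S, the differential-expression
#' baseline, and differential expression fused with the interaction
#' degree. The TF universe is the set of TFs in the filtered prior that
#' are present in the expression matrix.
#'
#' @param cfg A [run_config()].
#' @return List of class `pipeline_result`: `reports` (named
#'   `enrichment_report`s), `combined` (score table), `grn`, `universe`,
#'   `manifest` (seeds, versions, timings, output hashes).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tim <- new.env(); tim$timings <- list()

  inputs <- run_stage("load", tim, {
    list(expression = resolve_input(cfg$expression, read_expression),
         prior = resolve_input(cfg$prior, read_prior),
         ppi = resolve_input(cfg$ppi, read_ppi),
         drivers = {
           d <- resolve_input(cfg$drivers, read_gene_sets)
           if (is.list(d)) d[[1L]] else d
         },
         growth = if (!is.null(cfg$growth)) resolve_input(cfg$growth, read_growth))
  })

  expr <- run_stage("preprocess", tim, {
    m <- inputs$expression
    if (!is.null(inputs$growth) && !is.null(cfg$growth_conditions)) {
      keep <- select_samples_by_score(inputs$growth, cfg$growth_conditions,
                                      cfg$growth_cutoff)
      keep <- intersect(colnames(m), keep)
      if (length(keep)) m <- m[, keep, drop = FALSE]
    }
    m <- filter_missing(m, cfg$max_missing)
    knn_impute(m, cfg$knn_k)
  })

  prior <- run_stage("filter_prior", tim, filter_prior(inputs$prior, cfg$prior_alpha))

  grn <- run_stage("infer_grn", tim, infer_network(expr, prior, cfg$inference))

  universe <- sort(intersect(unique(prior$tf), rownames(expr)))
  if (!length(universe)) stop("pipeline stage 'score' failed: empty TF universe")

  seeds <- derive_seeds(cfg$scoring_seed, 2L)
  scored <- run_stage("score", tim, {
    rt <- rank_degrees(network_degree(grn, universe), universe, seeds[[1L]])
    rp <- rank_degrees(network_degree(inputs$ppi, universe), universe, seeds[[2L]])
    list(rt = rt, rp = rp, combined = combined_score(rt, rp, universe))
  })

  de <- run_stage("diff_expression", tim, {
    ga <- cfg$group_a %||% colnames(expr)[seq_len(ceiling(ncol(expr) / 2))]
    gb <- cfg$group_b %||% setdiff(colnames(expr), ga)
    ga <- intersect(ga, colnames(expr)); gb <- intersect(gb, colnames(expr))
    tab <- diff_expression(expr, ga, gb)
    rank_scores(stats::setNames(tab$p_value, tab$id), universe,
                decreasing = FALSE)
  })
  de_ppi <- combine_ranks(de, scored$rp, universe)

  rankings <- list(
    transcriptional = scored$rt[order(scored$rt$rank, scored$rt$id), "id"],
    ppi = scored$rp[order(scored$rp$rank, scored$rp$id), "id"],
    combined = scored$combined$id,
    diff_expr = de[order(de$rank, de$id), "id"],
    diff_expr_ppi = de_ppi$id)

  reports <- run_stage("enrich", tim, {
    lapply(rankings, enrichment_report, drivers = inputs$drivers,
           top_k = cfg$top_k)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("driverrank")),
    r_version = as.character(getRversion()),
    seeds = list(scoring = cfg$scoring_seed,
                 inference = cfg$inference$seed),
    parameters = list(prior_alpha = cfg$prior_alpha,
                      max_missing = cfg$max_missing, knn_k = cfg$knn_k,
                      alpha = cfg$inference$alpha,
                      n_bins = cfg$inference$n_bins,
                      max_candidates = cfg$inference$max_candidates,
                      top_k = cfg$top_k),
    universe_size = length(universe),
    n_edges = nrow(grn),
    timings = tim$timings)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- c(expression = "expression.imputed.tsv", grn = "grn.tsv",
             combined = "combined_score.tsv", reports = "reports.json")
    out[] <- file.path(cfg$outdir, out)
    write_expression(expr, out[["expression"]])
    write_grn(grn, out[["grn"]])
    utils::write.table(scored$combined, out[["combined"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(reports, unclass), out[["reports"]],
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
    manifest$outputs <- lapply(out, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(reports = reports, combined = scored$combined,
                 rank_tables = list(transcriptional = scored$rt,
                                    ppi = scored$rp, diff_expr = de),
                 grn = grn, universe = universe, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$universe), "TFs,", nrow(x$grn),
      "inferred edges\n")
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-16s AUC = %.3f  Wilcoxon p = %.3g\n",
                nm, r$auc, r$p_wilcoxon))
  }
  invisible(x)
}
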