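#' Run the full redistribution analysis
#'
#' End-to-end pipeline: preprocessing (smoothing, normalization, condition
#' means), per-protein pairwise Jensen-Shannon distance matrices, ANOSIM R
#' with local (per-protein) and global (pooled-null) permutation p-values,
#' BH adjustment, shift metrics, the percentile R cutoff and the final
#' ranking.
#'
#' @param dataset an `fs_dataset`.
#' @param config an [analysis_config()].
#' @return An object of class `fs_analysis` with elements
#'   `results` (ranked per-protein table, see [rank_proteins()]),
#'   `candidates` (records passing the R cutoff), `null` (the pooled
#'   permutation null), `cutoff`, `profiles`, `config` and `counts`.
#' @examples
#' sim <- simulate_dataset(simulation_config(n_proteins = 12, seed = 7))
#' fit <- run_analysis(sim$dataset, analysis_config(seed = 7))
#' head(fit$results)
#' @export
run_analysis <- function(dataset, config = analysis_config()) {
  profiles <- build_profileset(dataset, config)
  dmats <- pairwise_distance_matrices(profiles, config$distance)
  treatment <- profiles$conditions[["treatment"]]

  if (length(dmats) == 0L) {
    stop_fs("no testable proteins in the dataset")
  }

  r_obs <- vapply(dmats, anosim_r, numeric(1L))
  p_local <- vapply(seq_along(dmats), function(k) {
    local_permutation_pvalue(
      dmats[[k]],
      mode = config$permutation_mode,
      n_monte_carlo = config$n_monte_carlo,
      seed = config$seed + k,
      treatment = treatment
    )
  }, numeric(1L))
  names(p_local) <- names(dmats)

  null <- global_null_distribution(dmats, config, treatment = treatment)
  gp <- global_pvalues(r_obs, null)

  sm <- shift_metrics(profiles, config)
  sm$anosim_r <- NA_real_
  sm$p_local <- NA_real_
  sm$p_global <- NA_real_
  sm$p_adj <- NA_real_
  idx <- match(gp$protein_id, sm$protein_id)
  sm$anosim_r[idx] <- gp$r
  sm$p_local[idx] <- p_local[gp$protein_id]
  sm$p_global[idx] <- gp$p_global
  sm$p_adj[idx] <- gp$p_adj

  ranked <- rank_proteins(sm)
  cutoff <- r_cutoff(null, config$cutoff_percentile)
  candidates <- candidate_table(ranked, cutoff)

  structure(
    list(
      results = ranked,
      candidates = candidates,
      null = null,
      cutoff = cutoff,
      profiles = profiles,
      config = config,
      counts = list(
        proteins = length(profiles$testable),
        testable = sum(profiles$testable),
        passing_cutoff = attr(candidates, "n_passing")
      )
    ),
    class = "fs_analysis"
  )
}

#' @export
print.fs_analysis <- function(x, ...) {
  cat(sprintf(
    "<fs_analysis> %d proteins (%d testable), R cutoff %.4f (%g percentile), %d passing\n",
    x$counts$proteins, x$counts$testable, x$cutoff,
    x$config$cutoff_percentile, x$counts$passing_cutoff
  ))
  invisible(x)
}

#' Write all analysis outputs to a directory
#'
#' Writes `results.tsv` (full ranked table), `candidates.tsv` (records at or
#' above the R cutoff), `bubble.tsv` (bubble-plot records), `export.json`
#' (the full JSON export, see [export_json()]) and `manifest.json` (config
#' echo, input digests, version, seed and counts).  Statistics columns are
#' deterministic for a fixed dataset, config and seed; the manifest's
#' timestamp is the only run-dependent field.
#'
#' @param analysis an `fs_analysis`.
#' @param dir output directory (created if needed).
#' @param input_paths optional named character vector of input file paths to
#'   digest into the manifest.
#' @param groups optional protein-set annotations for [bubbleplot_table()].
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir, input_paths = NULL, groups = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(analysis$results, file.path(dir, "results.tsv"))
  write_results_table(analysis$candidates, file.path(dir, "candidates.tsv"))

  bub <- bubbleplot_table(analysis$results, groups)
  utils::write.table(bub, file.path(dir, "bubble.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")

  export_json(analysis, file.path(dir, "export.json"))

  digests <- if (!is.null(input_paths)) {
    as.list(tools::md5sum(input_paths))
  } else {
    NULL
  }
  manifest <- list(
    tool = "fracshift",
    version = as.character(utils::packageVersion("fracshift")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = analysis$config$seed,
    config = unclass(analysis$config),
    inputs = digests,
    counts = analysis$counts,
    r_cutoff = analysis$cutoff
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
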