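.schema_version <- "1.0"

#' Export an analysis as a single JSON document
#'
#' Self-contained export: schema version, config echo, fraction axis,
#' sample table, per-protein records (normalized replicate profiles,
#' condition means and all statistics), the pooled null R values and the
#' derived cutoff.  Numbers are written at full precision so statistics
#' survive a round trip exactly; the schema is documented in the package
#' README.
#'
#' @param analysis an `fs_analysis` from [run_analysis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_json <- function(analysis, path) {
  profiles <- analysis$profiles
  res <- as.data.frame(analysis$results)
  ids <- res$protein_id
  pnames <- dimnames(profiles$profiles)[[1L]]

  protein_records <- lapply(seq_along(ids), function(k) {
    i <- match(ids[[k]], pnames)
    rec <- as.list(res[k, , drop = FALSE])
    rec <- lapply(rec, function(v) if (is.factor(v)) as.character(v) else v)
    reps <- profiles$profiles[i, , , drop = TRUE]
    rec$replicate_profiles <- lapply(
      seq_len(nrow(reps)),
      function(s) as.numeric(reps[s, ])
    )
    names(rec$replicate_profiles) <- profiles$samples$sample_id
    rec$mean_profiles <- list()
    for (ci in 1:2) {
      cond <- dimnames(profiles$means)[[2L]][ci]
      rec$mean_profiles[[cond]] <- as.numeric(profiles$means[i, ci, ])
    }
    rec$valid_samples <- as.logical(profiles$valid[i, ])
    rec
  })

  doc <- list(
    schema_version = .schema_version,
    tool = "fracshift",
    version = as.character(utils::packageVersion("fracshift")),
    config = unclass(analysis$config),
    fraction_axis = list(
      labels = profiles$axis$labels,
      mode = profiles$axis$mode,
      positions = profiles$axis$positions
    ),
    samples = profiles$samples,
    conditions = as.list(profiles$conditions),
    r_cutoff = analysis$cutoff,
    null = list(
      values = analysis$null$values,
      include_identity = analysis$null$include_identity,
      seed = analysis$null$seed
    ),
    proteins = protein_records
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read back a JSON export
#'
#' @param path path to a file written by [export_json()].
#' @return The parsed document (nested list; vectors simplified).  The
#'   `proteins` element holds one record per protein with its statistics
#'   and profiles; `null$values` holds the pooled permutation null.
#' @export
read_analysis_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$schema_version)) {
    stop_fs("not a fracshift export: missing schema_version")
  }
  doc
}

#' Extract the ranked statistics table from a JSON export
#'
#' @param doc parsed export from [read_analysis_json()].
#' @return Data frame with one row per protein, in the exported order.
#' @export
json_results_table <- function(doc) {
  scalar_cols <- c(
    "protein_id", "anosim_r", "effect_jsd", "S_plus", "S_minus",
    "relative_fraction_shift", "relative_distribution_change",
    "mean_within_jsd_treatment", "mean_within_jsd_control",
    "testable", "reason", "rank", "p_local", "p_global", "p_adj"
  )
  rows <- lapply(doc$proteins, function(rec) {
    vals <- lapply(scalar_cols, function(cl) {
      v <- rec[[cl]]
      if (is.null(v)) NA else v
    })
    names(vals) <- scalar_cols
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
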