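#' Rank proteins by decreasing ANOSIM R, then effect size
#'
#' Produces the candidate ranking: decreasing R, ties broken by decreasing
#' effect-size JSD, remaining ties by ascending protein identifier so the
#' order is total, stable and reproducible across runs and input row
#' orders.  Testable proteins receive ranks `1..N`; untestable proteins
#' follow with no rank and no statistics.
#'
#' @param stats data frame combining per-protein ANOSIM and shift metrics;
#'   must contain `protein_id`, `anosim_r`, `effect_jsd` and `testable`.
#' @return The reordered data frame with a `rank` column, class
#'   `fs_ranked`.
#' @export
rank_proteins <- function(stats) {
  req <- c("protein_id", "anosim_r", "effect_jsd", "testable")
  miss <- setdiff(req, names(stats))
  if (length(miss)) stop_fs("stats missing column(s): ", paste(miss, collapse = ", "))
  testable <- stats[stats$testable, , drop = FALSE]
  untestable <- stats[!stats$testable, , drop = FALSE]
  ord <- order(-testable$anosim_r, -testable$effect_jsd, testable$protein_id)
  testable <- testable[ord, , drop = FALSE]
  testable$rank <- seq_len(nrow(testable))
  untestable <- untestable[order(untestable$protein_id), , drop = FALSE]
  if (nrow(untestable)) untestable$rank <- NA_integer_
  out <- rbind(testable, untestable)
  rownames(out) <- NULL
  class(out) <- c("fs_ranked", "data.frame")
  out
}

#' Filter the ranking at an R cutoff
#'
#' @param ranked an `fs_ranked` table from [rank_proteins()].
#' @param r_cutoff threshold; testable proteins with `anosim_r >= r_cutoff`
#'   are kept, in rank order.
#' @return The filtered records, with the cutoff and the surviving count as
#'   attributes `r_cutoff` and `n_passing`.
#' @export
candidate_table <- function(ranked, r_cutoff) {
  keep <- ranked$testable & !is.na(ranked$anosim_r) & ranked$anosim_r >= r_cutoff
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "r_cutoff") <- r_cutoff
  attr(out, "n_passing") <- nrow(out)
  out
}

#' Bubble-plot table
#'
#' Plot-ready records for the standard redistribution overview: x = relative
#' fraction shift (empty on categorical axes), y = relative distribution
#' change (entropy gain/loss), bubble size = effect-size JSD, plus an
#' optional group tag for protein sets of interest.
#'
#' @param ranked an `fs_ranked` table.
#' @param groups optional named list of protein-identifier vectors; the
#'   first matching set names each protein's `group`.
#' @return Data frame with columns `protein_id`, `x`, `y`, `size`, `group`,
#'   `rank`.
#' @export
bubbleplot_table <- function(ranked, groups = NULL) {
  out <- data.frame(
    protein_id = ranked$protein_id,
    x = if ("relative_fraction_shift" %in% names(ranked)) {
      ranked$relative_fraction_shift
    } else {
      NA_real_
    },
    y = ranked$relative_distribution_change,
    size = ranked$effect_jsd,
    group = NA_character_,
    rank = ranked$rank,
    stringsAsFactors = FALSE
  )
  if (!is.null(groups)) {
    for (g in names(groups)) {
      hit <- out$protein_id %in% groups[[g]] & is.na(out$group)
      out$group[hit] <- g
    }
  }
  out
}

.results_columns <- c(
  "protein_id", "anosim_r", "effect_jsd", "relative_fraction_shift",
  "relative_distribution_change", "rank", "p_global", "p_adj",
  "testable_flag", "p_local", "mean_within_jsd_treatment",
  "mean_within_jsd_control", "reason"
)

#' Write the ranked results table
#'
#' Tab-delimited, one row per protein in rank order (untestable proteins
#' last, flagged `false` with empty statistic cells).  Numbers are written
#' with 15 significant digits so a read-back reproduces values to at least
#' 12 significant digits.
#'
#' @param ranked an `fs_ranked` table from [rank_proteins()] (typically via
#'   [run_analysis()], so the p-value columns are present).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(ranked, path) {
  df <- as.data.frame(ranked)
  df$testable_flag <- ifelse(df$testable, "true", "false")
  for (col in .results_columns) if (!col %in% names(df)) df[[col]] <- NA
  df <- df[, .results_columns, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "", formatC(x, digits = 15, format = "g"))
  })
  df[is.na(df)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path path to the TSV.
#' @return Data frame with numeric statistic columns and logical `testable`.
#' @export
read_results_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  df$testable <- df$testable_flag == "true"
  df
}
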