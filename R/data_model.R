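#' Fraction axis
#'
#' Describes the ordered set of fractions a profile is measured over.  In
#' `"continuous"` mode (density gradients, size-exclusion columns) fractions
#' carry integer coordinates `1..F` in label order and shift positions are
#' meaningful; in `"categorical"` mode (subcellular compartments) fraction
#' labels are unordered bins, the smoothing kernel is disabled and positional
#' shift metrics are not applicable.
#'
#' @param labels character vector of unique, non-empty fraction identifiers
#'   (at least two).
#' @param mode `"continuous"` (default) or `"categorical"`.
#' @return An object of class `fraction_axis` with elements `labels`, `mode`
#'   and, in continuous mode, integer `positions` `1..F`.
#' @examples
#' fraction_axis(paste0("F", 1:20))
#' fraction_axis(c("nucleus", "cytosol", "membrane"), mode = "categorical")
#' @export
fraction_axis <- function(labels, mode = c("continuous", "categorical")) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  if (length(labels) < 2L) {
    stop_fs("a fraction axis needs at least 2 fractions, got ", length(labels))
  }
  if (anyDuplicated(labels) || any(!nzchar(labels)) || anyNA(labels)) {
    stop_fs("fraction labels must be unique and non-empty")
  }
  structure(
    list(
      labels = labels,
      mode = mode,
      positions = if (mode == "continuous") seq_along(labels) else NULL
    ),
    class = "fraction_axis"
  )
}

#' @export
print.fraction_axis <- function(x, ...) {
  cat(sprintf(
    "<fraction_axis> %d fractions (%s): %s%s\n",
    length(x$labels), x$mode,
    paste(utils::head(x$labels, 5), collapse = ", "),
    if (length(x$labels) > 5) ", ..." else ""
  ))
  invisible(x)
}

#' Sample design
#'
#' Validates and stores the mapping from measurement columns of an intensity
#' table to `(condition, replicate, fraction)` triples.  Exactly two
#' conditions are required; each `(condition, replicate)` pair must cover
#' every fraction exactly once, and each condition needs at least two
#' replicates so that within-condition dissimilarities exist.
#'
#' @param entries data frame with columns `sample` (measurement column name),
#'   `condition`, `replicate` (positive integer) and `fraction`; an optional
#'   `order` column fixes the fraction ordering, otherwise order of first
#'   appearance is used.
#' @param treatment which condition label plays the role of the treatment
#'   (the `+` group for sign conventions of the shift metrics).  Defaults to
#'   a label literally named `"treatment"` if present, otherwise the first
#'   condition encountered (with a message).
#' @return An object of class `sample_design`: the validated `entries` plus
#'   attributes `treatment`, `control`, `fraction_labels`, `n_treatment`,
#'   `n_control` and a `samples` table with one row per
#'   `(condition, replicate)` pair.
#' @seealso [read_design()] to build one from a delimited file.
#' @export
sample_design <- function(entries, treatment = NULL) {
  req <- c("sample", "condition", "replicate", "fraction")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols)) {
    stop_fs("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  entries$sample <- as.character(entries$sample)
  entries$condition <- as.character(entries$condition)
  entries$fraction <- as.character(entries$fraction)
  entries$replicate <- as.integer(entries$replicate)
  if (anyNA(entries$replicate) || any(entries$replicate < 1L)) {
    stop_fs("replicate must be a positive integer")
  }

  conds <- unique(entries$condition)
  if (length(conds) != 2L) {
    stop_fs(
      "exactly two condition labels are required, found: ",
      paste(conds, collapse = ", ")
    )
  }
  if (is.null(treatment)) {
    if ("treatment" %in% conds) {
      treatment <- "treatment"
    } else {
      treatment <- conds[[1L]]
      message(
        "no treatment label nominated; using first condition ",
        sQuote(treatment), " as treatment"
      )
    }
  }
  if (!treatment %in% conds) {
    stop_fs(
      "treatment label ", sQuote(treatment), " not among conditions: ",
      paste(sQuote(conds), collapse = ", ")
    )
  }
  control <- setdiff(conds, treatment)

  if ("order" %in% names(entries)) {
    ord <- entries[!duplicated(entries$fraction), c("fraction", "order")]
    fraction_labels <- ord$fraction[order(ord$order)]
  } else {
    fraction_labels <- unique(entries$fraction)
  }

  key <- paste(entries$condition, entries$replicate, entries$fraction, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop_fs(
      "duplicate design row for (condition=", entries$condition[bad],
      ", replicate=", entries$replicate[bad],
      ", fraction=", entries$fraction[bad], ") at row ", bad
    )
  }
  if (anyDuplicated(entries$sample)) {
    stop_fs("duplicate sample column name in design: ",
            entries$sample[duplicated(entries$sample)][1L])
  }

  pair_key <- paste(entries$condition, entries$replicate, sep = "\r")
  for (pk in unique(pair_key)) {
    have <- entries$fraction[pair_key == pk]
    miss <- setdiff(fraction_labels, have)
    if (length(miss)) {
      parts <- strsplit(pk, "\r", fixed = TRUE)[[1L]]
      stop_fs(
        "incomplete design: (condition=", parts[1L], ", replicate=", parts[2L],
        ") is missing fraction(s) ", paste(miss, collapse = ", ")
      )
    }
  }

  samples <- unique(entries[, c("condition", "replicate")])
  samples <- samples[order(match(samples$condition, c(treatment, control)),
                           samples$replicate), , drop = FALSE]
  samples$sample_id <- paste(samples$condition, samples$replicate, sep = ".")
  rownames(samples) <- NULL
  n_t <- sum(samples$condition == treatment)
  n_c <- sum(samples$condition == control)
  if (n_t < 2L || n_c < 2L) {
    stop_fs(
      "at least 2 replicates per condition are required (found ",
      n_t, " treatment, ", n_c, " control)"
    )
  }

  structure(
    entries,
    treatment = treatment,
    control = control,
    fraction_labels = fraction_labels,
    samples = samples,
    n_treatment = n_t,
    n_control = n_c,
    class = c("sample_design", "data.frame")
  )
}

#' Read a sample design table
#'
#' Reads a delimited file (TSV, or CSV for a `.csv` extension) with header
#' columns `sample`, `condition`, `replicate`, `fraction` and an optional
#' `order` column, and validates it via [sample_design()].
#'
#' @param path path to the design file.
#' @inheritParams sample_design
#' @return A validated [sample_design()] object.
#' @export
read_design <- function(path, treatment = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  sample_design(df, treatment = treatment)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the redistribution analysis.  The
#' logarithm base of all information-theoretic quantities is fixed at 2, so
#' distances live in `[0, 1]` and entropies are in bits.
#'
#' @param kernel_size odd positive integer width of the moving-average
#'   smoothing kernel (default 3).  Forced to 1 for categorical fraction
#'   axes, where smoothing across unordered bins is meaningless.
#' @param beta positive soft-argmax temperature; larger values move the
#'   expected peak position towards the hard argmax.
#' @param permutation_mode `"exact"` (enumerate all distinct label
#'   assignments) or `"monte_carlo"`.
#' @param n_monte_carlo number of random label draws in Monte-Carlo mode.
#' @param exact_limit largest per-protein assignment count for which exact
#'   enumeration is used before falling back to Monte-Carlo sampling.
#' @param seed integer seed for every stochastic step.
#' @param cutoff_percentile percentile (in `(0, 100]`) of the pooled null R
#'   distribution used as the candidate cutoff (default 95).
#' @param alpha nominal significance level, used for reporting only.
#' @param include_identity_in_null should the observed (identity) label
#'   assignment contribute to the pooled global null?  Default `FALSE`.
#' @param distance name of the registered profile distance (default
#'   `"jsd"`, the Jensen-Shannon distance; see [register_distance()]).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(kernel_size = 3L,
                            beta = 1,
                            permutation_mode = c("exact", "monte_carlo"),
                            n_monte_carlo = 999L,
                            exact_limit = 10000L,
                            seed = 1L,
                            cutoff_percentile = 95,
                            alpha = 0.05,
                            include_identity_in_null = FALSE,
                            distance = "jsd") {
  permutation_mode <- match.arg(permutation_mode)
  kernel_size <- as.integer(kernel_size)
  if (is.na(kernel_size) || kernel_size < 1L || kernel_size %% 2L == 0L) {
    stop_fs("kernel_size must be an odd positive integer, got ", kernel_size)
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop_fs("beta must be a single positive number")
  }
  if (cutoff_percentile <= 0 || cutoff_percentile > 100) {
    stop_fs("cutoff_percentile must be in (0, 100]")
  }
  structure(
    list(
      kernel_size = kernel_size,
      beta = beta,
      log_base = 2L,
      permutation_mode = permutation_mode,
      n_monte_carlo = as.integer(n_monte_carlo),
      exact_limit = as.integer(exact_limit),
      seed = as.integer(seed),
      cutoff_percentile = cutoff_percentile,
      alpha = alpha,
      include_identity_in_null = isTRUE(include_identity_in_null),
      distance = distance
    ),
    class = "analysis_config"
  )
}

new_dataset <- function(intensities, axis, design, annotations = NULL) {
  structure(
    list(
      proteins = dimnames(intensities)[[1L]],
      intensities = intensities,
      axis = axis,
      design = design,
      samples = attr(design, "samples"),
      annotations = annotations
    ),
    class = "fs_dataset"
  )
}

#' @export
print.fs_dataset <- function(x, ...) {
  s <- attr(x$design, "samples")
  cat(sprintf(
    "<fs_dataset> %d proteins x %d samples (%d %s + %d %s) x %d fractions (%s)\n",
    length(x$proteins), nrow(s),
    attr(x$design, "n_treatment"), attr(x$design, "treatment"),
    attr(x$design, "n_control"), attr(x$design, "control"),
    length(x$axis$labels), x$axis$mode
  ))
  invisible(x)
}

#' Read a protein intensity table
#'
#' Reads a delimited intensity matrix (one row per protein, one column per
#' sample-fraction measurement) and assembles it into a dataset following a
#' validated design.  Column matching is strictly by name: every `sample`
#' entry of the design must name a column.  Empty cells and `NA` are recorded
#' as missing (not zero); negative intensities are rejected.
#'
#' @param path path to a TSV (or CSV for a `.csv` extension) file.
#' @param design a [sample_design()].
#' @param mode fraction-axis mode, `"continuous"` or `"categorical"`.
#' @param id_col name of the protein-identifier column; defaults to the
#'   first column.
#' @return An object of class `fs_dataset` holding the intensity tensor
#'   indexed `(protein, sample, fraction)` with `NA` marking missing values,
#'   plus the fraction axis and design.  Columns of the input table that are
#'   neither the id column nor design measurements are kept as annotations.
#' @export
read_intensity_table <- function(path, design,
                                 mode = c("continuous", "categorical"),
                                 id_col = NULL) {
  mode <- match.arg(mode)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  if (is.null(id_col)) id_col <- names(df)[[1L]]
  if (!id_col %in% names(df)) {
    stop_fs("id column ", sQuote(id_col), " not found in ", path)
  }
  as_dataset(df, design, mode = mode, id_col = id_col)
}

#' Assemble a dataset from an in-memory intensity table
#'
#' @param table data frame with a protein-identifier column and one numeric
#'   column per design entry (`NA` marks missing measurements).
#' @inheritParams read_intensity_table
#' @return An `fs_dataset`; see [read_intensity_table()].
#' @export
as_dataset <- function(table, design, mode = c("continuous", "categorical"),
                       id_col = NULL) {
  mode <- match.arg(mode)
  if (!inherits(design, "sample_design")) {
    stop_fs("design must be a sample_design object")
  }
  if (is.null(id_col)) id_col <- names(table)[[1L]]
  ids <- as.character(table[[id_col]])
  if (anyDuplicated(ids)) {
    stop_fs("duplicate protein identifier: ", ids[duplicated(ids)][1L])
  }
  absent <- setdiff(design$sample, names(table))
  if (length(absent)) {
    stop_fs(
      "design column(s) absent from intensity table: ",
      paste(utils::head(absent, 5), collapse = ", "),
      if (length(absent) > 5) " ..." else ""
    )
  }

  axis <- fraction_axis(attr(design, "fraction_labels"), mode = mode)
  samples <- attr(design, "samples")
  n <- length(ids)
  S <- nrow(samples)
  F_ <- length(axis$labels)

  arr <- array(
    NA_real_,
    dim = c(n, S, F_),
    dimnames = list(ids, samples$sample_id, axis$labels)
  )
  for (k in seq_len(nrow(design))) {
    col <- design$sample[k]
    v <- as.numeric(table[[col]])
    neg <- which(!is.na(v) & v < 0)
    if (length(neg)) {
      stop_fs(
        "negative intensity for protein ", sQuote(ids[neg[1L]]),
        " in column ", sQuote(col)
      )
    }
    sid <- paste(design$condition[k], design$replicate[k], sep = ".")
    arr[, sid, design$fraction[k]] <- v
  }

  extra <- setdiff(names(table), c(id_col, design$sample))
  annotations <- if (length(extra)) {
    a <- table[, extra, drop = FALSE]
    rownames(a) <- ids
    a
  } else {
    NULL
  }
  new_dataset(arr, axis, design, annotations)
}
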