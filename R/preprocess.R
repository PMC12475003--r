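#' Smooth an intensity profile with a uniform moving average
#'
#' Applies a centred moving-average kernel of odd width along the fraction
#' axis, padding with zeros outside the measured range: no protein mass
#' exists beyond the gradient, and any mass the window loses at the
#' boundaries is restored by the subsequent normalization.  `kernel_size = 1`
#' is the identity, and is the mandatory setting for categorical fraction
#' axes where neighbouring bins are not ordered.
#'
#' @param raw non-negative numeric vector of intensities over fractions.
#' @param kernel_size odd positive integer window width.
#' @return Numeric vector of the same length.
#' @examples
#' smooth_profile(c(0, 3, 0, 0), 3)  # c(1, 1, 1, 0)
#' @export
smooth_profile <- function(raw, kernel_size) {
  kernel_size <- as.integer(kernel_size)
  if (is.na(kernel_size) || kernel_size < 1L || kernel_size %% 2L == 0L) {
    stop_fs("kernel_size must be an odd positive integer, got ", kernel_size)
  }
  if (any(raw < 0, na.rm = TRUE)) stop_fs("intensities must be non-negative")
  if (kernel_size == 1L) return(raw)
  h <- kernel_size %/% 2L
  padded <- c(rep(0, h), raw, rep(0, h))
  out <- as.numeric(stats::filter(padded, rep(1 / kernel_size, kernel_size),
                                  sides = 2))
  out[(h + 1L):(h + length(raw))]
}

#' Normalize a profile to a probability distribution
#'
#' Divides a smoothed non-negative profile by its total so it sums to one.
#' An all-zero profile carries no distributional information and cannot be
#' normalized; it is returned as all-`NA`, which downstream code treats as an
#' invalid sample rather than an error.
#'
#' @param smoothed non-negative numeric vector.
#' @return A probability vector summing to 1, or an all-`NA` vector of the
#'   same length if the input is all zero.
#' @export
normalize_profile <- function(smoothed) {
  if (any(smoothed < 0, na.rm = TRUE)) {
    stop_fs("profiles must be non-negative before normalization")
  }
  s <- sum(smoothed)
  if (!is.finite(s) || s <= 0) {
    return(rep(NA_real_, length(smoothed)))
  }
  smoothed / s
}

#' Build smoothed, normalized replicate and mean distributions
#'
#' Converts the raw intensity tensor into per-sample probability
#' distributions and per-condition mean distributions.  Missing measurements
#' are treated as zero intensity immediately before smoothing (absence of
#' signal is taken as evidence of absence at the profile level; a message
#' reports how many cells were affected).  Samples whose profile is entirely
#' zero are marked invalid; a protein is testable only while both conditions
#' retain at least two valid samples, and untestable proteins carry an
#' explicit reason.
#'
#' Condition means are arithmetic means of the valid replicate distributions
#' only, so they stay on the probability simplex when samples are dropped.
#'
#' @param dataset an `fs_dataset` from [read_intensity_table()] /
#'   [as_dataset()] or [simulate_dataset()].
#' @param config an [analysis_config()]; `kernel_size` is forced to 1 for
#'   categorical axes.
#' @return An object of class `fs_profileset` with elements
#'   `profiles` (`protein x sample x fraction` array, `NA` rows for invalid
#'   samples), `valid` (logical `protein x sample`), `means`
#'   (`protein x condition x fraction`, treatment first), `n_valid`
#'   (`protein x condition` counts), `testable`, `reason`, the fraction
#'   `axis`, the `samples` table and the condition labels.
#' @export
build_profileset <- function(dataset, config = analysis_config()) {
  if (!inherits(dataset, "fs_dataset")) stop_fs("dataset must be an fs_dataset")
  axis <- dataset$axis
  kernel <- config$kernel_size
  if (axis$mode == "categorical" && kernel != 1L) {
    message("categorical fraction axis: smoothing kernel disabled (kernel_size = 1)")
    kernel <- 1L
  }
  arr <- dataset$intensities
  n_missing <- sum(is.na(arr))
  if (n_missing > 0) {
    message(
      "treating ", n_missing,
      " missing intensity cell(s) as zero before smoothing"
    )
    arr[is.na(arr)] <- 0
  }

  samples <- dataset$samples
  treatment <- attr(dataset$design, "treatment")
  control <- attr(dataset$design, "control")
  n <- dim(arr)[1L]; S <- dim(arr)[2L]; F_ <- dim(arr)[3L]

  profiles <- array(NA_real_, dim = dim(arr), dimnames = dimnames(arr))
  valid <- matrix(FALSE, n, S, dimnames = dimnames(arr)[1:2])
  for (i in seq_len(n)) {
    for (s in seq_len(S)) {
      p <- normalize_profile(smooth_profile(arr[i, s, ], kernel))
      profiles[i, s, ] <- p
      valid[i, s] <- !anyNA(p)
    }
  }

  cond_of <- samples$condition
  n_valid <- cbind(
    rowSums(valid[, cond_of == treatment, drop = FALSE]),
    rowSums(valid[, cond_of == control, drop = FALSE])
  )
  dimnames(n_valid) <- list(dimnames(arr)[[1L]], c(treatment, control))

  means <- array(
    NA_real_,
    dim = c(n, 2L, F_),
    dimnames = list(dimnames(arr)[[1L]], c(treatment, control), axis$labels)
  )
  testable <- rep(TRUE, n)
  reason <- rep("", n)
  for (i in seq_len(n)) {
    for (ci in 1:2) {
      cond <- c(treatment, control)[ci]
      keep <- which(cond_of == cond & valid[i, ])
      if (length(keep) >= 1L) {
        sub <- profiles[i, keep, , drop = FALSE]
        means[i, ci, ] <- apply(sub, 3L, mean)
      }
      if (length(keep) < 2L) {
        testable[i] <- FALSE
        reason[i] <- paste0(
          reason[i], if (nzchar(reason[i])) "; " else "",
          "fewer than 2 valid samples in ", cond
        )
      }
    }
  }

  structure(
    list(
      profiles = profiles,
      valid = valid,
      means = means,
      n_valid = n_valid,
      testable = testable,
      reason = reason,
      axis = axis,
      samples = samples,
      conditions = c(treatment = treatment, control = control),
      kernel_size = kernel
    ),
    class = "fs_profileset"
  )
}

#' @export
print.fs_profileset <- function(x, ...) {
  cat(sprintf(
    "<fs_profileset> %d proteins (%d testable), %d samples, %d fractions, kernel %d\n",
    length(x$testable), sum(x$testable), nrow(x$samples),
    length(x$axis$labels), x$kernel_size
  ))
  invisible(x)
}
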