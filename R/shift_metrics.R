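#' Position-wise relative entropy (bits)
#'
#' Decomposes the KL divergence of a distribution `P` to a mixture `M` into
#' per-fraction contributions `w(x) = P(x) log2(P(x) / M(x))` (0 where
#' `P(x) = 0`), so `sum(w) = D(P || M)`.  Fractions contributing most to the
#' divergence are where the distribution changed most; the vector feeds the
#' soft-argmax peak localisation.  `M` must have support wherever `P` does —
#' guaranteed when `M` is the mixture of `P` with anything — otherwise the
#' contract is violated and an error is raised.
#'
#' @param p probability vector.
#' @param m mixture probability vector of the same length.
#' @return Numeric vector of per-position contributions, in bits.
#' @export
positionwise_relative_entropy <- function(p, m) {
  if (length(p) != length(m)) {
    stop_fs("length mismatch: ", length(p), " vs ", length(m))
  }
  if (any(p > 0 & m == 0)) {
    stop_fs("mixture has zero mass where the distribution is positive; ",
            "m must be a mixture containing p")
  }
  w <- numeric(length(p))
  pos <- p > 0
  w[pos] <- p[pos] * log2(p[pos] / m[pos])
  w
}

#' Temperature-scaled soft-argmax position
#'
#' Expected position under a softmax over temperature-scaled scores:
#' `S = sum_x softmax(beta * w)(x) * x`.  As `beta` grows the softmax
#' concentrates on the maximal score and `S` converges to the hard argmax;
#' small `beta` averages over plateau-like score profiles instead of picking
#' an arbitrary winner.  The result always lies inside the position range.
#'
#' @param w numeric score vector (position-wise relative entropies).
#' @param beta positive temperature scale.
#' @param positions numeric positions, default `1..length(w)`; requires an
#'   ordered (continuous) fraction axis.
#' @return Real position in `[min(positions), max(positions)]`.
#' @examples
#' soft_argmax_position(c(0, 1), beta = 1)  # ~1.731
#' @export
soft_argmax_position <- function(w, beta = 1, positions = seq_along(w)) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop_fs("beta must be a single positive number")
  }
  if (length(w) != length(positions)) {
    stop_fs("w and positions must have equal length")
  }
  z <- beta * w
  z <- exp(z - max(z))
  sum(z / sum(z) * positions)
}

.mean_pair <- function(profiles, protein) {
  idx <- match(protein, dimnames(profiles$profiles)[[1L]])
  if (is.na(idx)) stop_fs("unknown protein ", sQuote(protein))
  if (!profiles$testable[idx]) {
    stop_fs("protein ", sQuote(protein), " is not testable (",
            profiles$reason[idx], ")")
  }
  list(plus = profiles$means[idx, 1L, ], minus = profiles$means[idx, 2L, ])
}

#' Effect size: Jensen-Shannon distance between condition means
#'
#' @param profiles an `fs_profileset`.
#' @param protein protein identifier (must be testable).
#' @return JSD between the treatment and control mean distributions, in
#'   `[0, 1]`.
#' @export
effect_size_jsd <- function(profiles, protein) {
  m <- .mean_pair(profiles, protein)
  jensen_shannon_distance(m$plus, m$minus)
}

#' Relative fraction shift via soft-argmax peak positions
#'
#' Locates the expected position of the strongest change in each condition
#' and subtracts them.  Both conditions are scored against the shared
#' mixture of the two mean distributions: `w_t = P_t log2(P_t / M)`
#' position-wise, `S_t` its soft-argmax, and the relative fraction shift is
#' `S_plus - S_minus`.  Negative values are leftward shifts (towards lower
#' fraction numbers, i.e. lighter material after treatment).  Only defined
#' on continuous fraction axes.
#'
#' @inheritParams effect_size_jsd
#' @param beta soft-argmax temperature.
#' @return List with `S_plus`, `S_minus`, `rps` (the shift, in fractions)
#'   and the score vectors `w_plus`, `w_minus`.
#' @export
relative_fraction_shift <- function(profiles, protein, beta = 1) {
  if (profiles$axis$mode != "continuous") {
    stop_fs("relative fraction shift is not applicable to a categorical ",
            "fraction axis: positions are unordered")
  }
  m <- .mean_pair(profiles, protein)
  mix <- mixture_distribution(m$plus, m$minus)
  w_plus <- positionwise_relative_entropy(m$plus, mix)
  w_minus <- positionwise_relative_entropy(m$minus, mix)
  pos <- profiles$axis$positions
  s_plus <- soft_argmax_position(w_plus, beta, pos)
  s_minus <- soft_argmax_position(w_minus, beta, pos)
  list(
    S_plus = s_plus, S_minus = s_minus, rps = s_plus - s_minus,
    w_plus = w_plus, w_minus = w_minus
  )
}

#' Relative distribution change (entropy difference, bits)
#'
#' Shannon entropy of the treatment mean minus that of the control mean.
#' Positive values mean the protein's distribution broadened after
#' treatment; strongly negative values mean it collapsed into fewer
#' fractions.  Defined for both continuous and categorical axes.
#'
#' @inheritParams effect_size_jsd
#' @return Entropy difference in bits, within `[-log2(F), log2(F)]`.
#' @export
relative_distribution_change <- function(profiles, protein) {
  m <- .mean_pair(profiles, protein)
  shannon_entropy(m$plus) - shannon_entropy(m$minus)
}

#' Mean within-condition replicate distance
#'
#' Mean pairwise distance among one condition's valid replicate
#' distributions: a reproducibility diagnostic (low values mean consistent
#' replicates), not part of the ranking.
#'
#' @inheritParams effect_size_jsd
#' @param condition condition label.
#' @param distance registered distance name.
#' @return Mean pairwise distance, or `NA` when fewer than 2 valid samples
#'   exist in the condition.
#' @export
mean_within_jsd <- function(profiles, protein, condition, distance = "jsd") {
  idx <- match(protein, dimnames(profiles$profiles)[[1L]])
  if (is.na(idx)) stop_fs("unknown protein ", sQuote(protein))
  dist_fn <- distance_function(distance)
  keep <- which(profiles$valid[idx, ] & profiles$samples$condition == condition)
  if (length(keep) < 2L) return(NA_real_)
  P <- profiles$profiles[idx, keep, , drop = FALSE]
  pairs <- utils::combn(length(keep), 2L)
  mean(vapply(
    seq_len(ncol(pairs)),
    function(k) dist_fn(P[1L, pairs[1L, k], ], P[1L, pairs[2L, k], ]),
    numeric(1L)
  ))
}

#' Shift metrics for every protein
#'
#' Computes, per testable protein, the effect-size JSD between condition
#' means, the soft-argmax peak positions and relative fraction shift
#' (continuous axes only), the relative distribution change, and the mean
#' within-condition replicate distances.  Untestable proteins yield `NA`
#' rows.
#'
#' @param profiles an `fs_profileset`.
#' @param config an [analysis_config()] supplying `beta` and the distance.
#' @return Data frame with one row per protein: `protein_id`, `effect_jsd`,
#'   `S_plus`, `S_minus`, `relative_fraction_shift`,
#'   `relative_distribution_change`, `mean_within_jsd_treatment`,
#'   `mean_within_jsd_control`, `testable`, `reason`.
#' @export
shift_metrics <- function(profiles, config = analysis_config()) {
  ids <- dimnames(profiles$profiles)[[1L]]
  continuous <- profiles$axis$mode == "continuous"
  treatment <- profiles$conditions[["treatment"]]
  control <- profiles$conditions[["control"]]
  out <- data.frame(
    protein_id = ids,
    effect_jsd = NA_real_,
    S_plus = NA_real_,
    S_minus = NA_real_,
    relative_fraction_shift = NA_real_,
    relative_distribution_change = NA_real_,
    mean_within_jsd_treatment = NA_real_,
    mean_within_jsd_control = NA_real_,
    testable = profiles$testable,
    reason = profiles$reason,
    stringsAsFactors = FALSE
  )
  for (k in which(profiles$testable)) {
    p <- ids[[k]]
    out$effect_jsd[k] <- effect_size_jsd(profiles, p)
    out$relative_distribution_change[k] <-
      relative_distribution_change(profiles, p)
    if (continuous) {
      rfs <- relative_fraction_shift(profiles, p, beta = config$beta)
      out$S_plus[k] <- rfs$S_plus
      out$S_minus[k] <- rfs$S_minus
      out$relative_fraction_shift[k] <- rfs$rps
    }
    out$mean_within_jsd_treatment[k] <-
      mean_within_jsd(profiles, p, treatment, config$distance)
    out$mean_within_jsd_control[k] <-
      mean_within_jsd(profiles, p, control, config$distance)
  }
  out
}
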