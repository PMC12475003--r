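#' Midranks of the lower-triangle dissimilarities
#'
#' ANOSIM operates on the ranks of the `n(n-1)/2` pairwise dissimilarities;
#' ties receive midranks (average ranks), the standard convention for
#' rank-based statistics.
#'
#' @param d symmetric dissimilarity matrix.
#' @return Numeric vector of ranks of `d[lower.tri(d)]`.
#' @examples
#' m <- matrix(0, 3, 3); m[lower.tri(m)] <- c(1, 2, 2)
#' rank_dissimilarities(m + t(m))  # 1, 2.5, 2.5
#' @export
rank_dissimilarities <- function(d) {
  rank(d[lower.tri(d)], ties.method = "average")
}

# Shared machinery: given the ranked lower triangle and the (row, col) index
# pairs, evaluate R for one treatment-index set.
.anosim_r_core <- function(r, pair_i, pair_j, is_treat) {
  between <- is_treat[pair_i] != is_treat[pair_j]
  (mean(r[between]) - mean(r[!between])) / (length(r) / 2)
}

.pair_index <- function(n) {
  which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
}

#' ANOSIM R statistic for a two-group dissimilarity matrix
#'
#' `R = (rB - rW) / ((n(n-1)/2) / 2)` where `rB` and `rW` are the mean
#' midranks of between-group and within-group dissimilarities and `n` is the
#' total sample count.  `R` lies in `[-1, 1]`; 1 means every
#' between-condition dissimilarity exceeds every within-condition one
#' (perfect separation), values near 0 mean the ranks are interleaved, and
#' negative values mean within-condition pairs are the more dissimilar.
#' Being rank-based, `R` is invariant under any strictly increasing
#' transform of the dissimilarities.
#'
#' @param d symmetric dissimilarity matrix (any `attr(d, "condition")` is
#'   used when `labels` is missing).
#' @param labels vector of two distinct group labels, one per sample; each
#'   group needs at least 2 samples.
#' @return The R statistic, a real in `[-1, 1]`.
#' @export
anosim_r <- function(d, labels = attr(d, "condition")) {
  n <- nrow(d)
  if (is.null(labels) || length(labels) != n) {
    stop_fs("labels must supply one group per sample")
  }
  tab <- table(labels)
  if (length(tab) != 2L) stop_fs("exactly two groups are required")
  if (any(tab < 2L)) {
    stop_fs("each group needs at least 2 samples, got ",
            paste(tab, collapse = " and "))
  }
  r <- rank_dissimilarities(d)
  ij <- .pair_index(n)
  .anosim_r_core(r, ij[, 1L], ij[, 2L], labels == labels[[1L]])
}

#' Enumerate distinct two-group label assignments
#'
#' All distinct ways to assign `n_treatment + n_control` samples to two
#' groups of the given sizes.  Because the R statistic is symmetric in the
#' group labels, balanced designs count each assignment and its complement
#' once: the balanced count is `(2n)! / (2 (n!)^2)` (10 for 3 vs 3) while
#' unbalanced designs give the plain binomial coefficient.  The identity
#' assignment (the observed labelling, treatment = first `n_treatment`
#' samples) is always first.
#'
#' @param n_treatment,n_control group sizes, both at least 2.
#' @return List of integer vectors; each holds the sample indices assigned
#'   to the treatment group.
#' @examples
#' length(enumerate_label_assignments(3, 3))  # 10
#' @export
enumerate_label_assignments <- function(n_treatment, n_control) {
  n_treatment <- as.integer(n_treatment)
  n_control <- as.integer(n_control)
  if (n_treatment < 2L || n_control < 2L) {
    stop_fs("both groups need at least 2 samples")
  }
  n <- n_treatment + n_control
  subsets <- utils::combn(n, n_treatment, simplify = FALSE)
  if (n_treatment == n_control) {
    # complement-equivalent pairs collapse; keep the member containing
    # sample 1 as the canonical representative
    subsets <- Filter(function(s) 1L %in% s, subsets)
  }
  identity <- seq_len(n_treatment)
  is_id <- vapply(subsets, function(s) identical(s, identity), logical(1L))
  c(subsets[is_id], subsets[!is_id])
}

#' Number of distinct label assignments
#'
#' Closed form for the size of [enumerate_label_assignments()]:
#' `(2n)! / (2 (n!)^2)` when balanced, `choose(n_t + n_c, n_t)` otherwise.
#'
#' @inheritParams enumerate_label_assignments
#' @return Integer count.
#' @export
n_label_assignments <- function(n_treatment, n_control) {
  k <- choose(n_treatment + n_control, n_treatment)
  if (n_treatment == n_control) k / 2 else k
}

# R statistic under every assignment in `assignments` (list of treatment
# index sets).  Ranks are computed once: relabelling never changes them.
.anosim_r_assignments <- function(d, assignments) {
  n <- nrow(d)
  r <- rank_dissimilarities(d)
  ij <- .pair_index(n)
  pi <- ij[, 1L]; pj <- ij[, 2L]
  denom <- length(r) / 2
  vapply(assignments, function(s) {
    is_treat <- logical(n)
    is_treat[s] <- TRUE
    between <- is_treat[pi] != is_treat[pj]
    (mean(r[between]) - mean(r[!between])) / denom
  }, numeric(1L))
}

# Reorder samples so treatment samples come first; returns the permuted
# matrix (identity assignment is then 1..n_t).
.canonical_order <- function(d, labels, treatment) {
  ord <- order(labels != treatment)
  list(d = d[ord, ord, drop = FALSE], labels = labels[ord])
}

#' Local (per-protein) permutation p-value
#'
#' Probability, under random relabelling of the samples, of an R statistic
#' at least as large as the observed one (one-sided: large R = group
#' separation).  In exact mode all distinct assignments are enumerated and
#' the identity is included, so `p >= 1 / n_assignments` and never 0 — with
#' 3 vs 3 replicates the floor is 0.1, which is why small designs cannot
#' reach significance protein by protein.  Monte-Carlo mode uses
#' `n_monte_carlo` seeded random assignments plus the identity.
#'
#' @param d symmetric dissimilarity matrix.
#' @param labels two-group label vector (defaults to `attr(d, "condition")`).
#' @param mode `"exact"` or `"monte_carlo"`.
#' @param n_monte_carlo draws in Monte-Carlo mode.
#' @param seed RNG seed for Monte-Carlo mode.
#' @param treatment label to treat as the treatment group (first label by
#'   default).
#' @return p-value in `(0, 1]`.
#' @export
local_permutation_pvalue <- function(d, labels = attr(d, "condition"),
                                     mode = c("exact", "monte_carlo"),
                                     n_monte_carlo = 999L, seed = NULL,
                                     treatment = labels[[1L]]) {
  mode <- match.arg(mode)
  can <- .canonical_order(d, labels, treatment)
  n_t <- sum(can$labels == treatment)
  n_c <- length(can$labels) - n_t
  r_obs <- anosim_r(can$d, can$labels)
  if (mode == "exact") {
    rs <- .anosim_r_assignments(can$d, enumerate_label_assignments(n_t, n_c))
    mean(rs >= r_obs)
  } else {
    n <- n_t + n_c
    rs <- with_seed(seed, {
      draws <- replicate(n_monte_carlo, sort(sample.int(n, n_t)),
                         simplify = FALSE)
      .anosim_r_assignments(can$d, draws)
    })
    (1 + sum(rs >= r_obs)) / (1 + n_monte_carlo)
  }
}

#' Pooled (global) permutation null distribution of R
#'
#' Small replicate numbers make per-protein permutation tests powerless, so
#' the R statistics of label permutations are pooled across all testable
#' proteins into one sampling null, under the assumption that permuted R
#' values of different proteins follow a common distribution.  Per protein,
#' all distinct assignments are enumerated when their count is at most
#' `config$exact_limit`, otherwise `config$n_monte_carlo` seeded random
#' assignments are drawn.  The identity (observed) assignment is excluded by
#' default so real signal does not contaminate the null; over a complete
#' enumeration with the identity included the pooled R values average to
#' zero exactly, by symmetry of the rank sums under relabelling.
#'
#' @param dmats named list of per-protein dissimilarity matrices, as from
#'   [pairwise_distance_matrices()] (each with its `condition` attribute).
#' @param config an [analysis_config()].
#' @param treatment treatment condition label; defaults to the first label
#'   of the first matrix.
#' @return An object of class `fs_null`: `values` (pooled R statistics),
#'   `per_protein` (counts contributed), `mode` per protein
#'   (`"exact"`/`"monte_carlo"`), `include_identity` and `seed`.
#' @export
global_null_distribution <- function(dmats, config = analysis_config(),
                                     treatment = NULL) {
  if (length(dmats) == 0L) stop_fs("no testable proteins: empty matrix list")
  if (is.null(treatment)) treatment <- attr(dmats[[1L]], "condition")[[1L]]
  include_id <- isTRUE(config$include_identity_in_null)

  pooled <- with_seed(config$seed, {
    lapply(dmats, function(d) {
      labels <- attr(d, "condition")
      can <- .canonical_order(d, labels, treatment)
      n_t <- sum(can$labels == treatment)
      n_c <- length(can$labels) - n_t
      count <- n_label_assignments(n_t, n_c)
      if (config$permutation_mode == "exact" && count <= config$exact_limit) {
        assignments <- enumerate_label_assignments(n_t, n_c)
        if (!include_id) assignments <- assignments[-1L]
        list(r = .anosim_r_assignments(can$d, assignments), mode = "exact")
      } else {
        n <- n_t + n_c
        draws <- replicate(config$n_monte_carlo, sort(sample.int(n, n_t)),
                           simplify = FALSE)
        list(r = .anosim_r_assignments(can$d, draws), mode = "monte_carlo")
      }
    })
  })

  structure(
    list(
      values = unlist(lapply(pooled, `[[`, "r"), use.names = FALSE),
      per_protein = vapply(pooled, function(x) length(x$r), integer(1L)),
      mode = vapply(pooled, `[[`, character(1L), "mode"),
      include_identity = include_id,
      seed = config$seed
    ),
    class = "fs_null"
  )
}

#' @export
print.fs_null <- function(x, ...) {
  cat(sprintf(
    "<fs_null> %d pooled R values from %d proteins (%s%s)\n",
    length(x$values), length(x$per_protein),
    paste(unique(x$mode), collapse = "+"),
    if (x$include_identity) ", identity included" else ""
  ))
  invisible(x)
}

#' Global permutation p-values with BH adjustment
#'
#' For each observed R the p-value is the add-one permutation estimator
#' `p = (1 + #\{null R >= R_obs\}) / (1 + N_null)`, one-sided and never
#' zero.  Benjamini-Hochberg adjustment is applied across the supplied
#' (testable) proteins.
#'
#' @param r_observed named numeric vector of observed R statistics.
#' @param null an `fs_null` from [global_null_distribution()].
#' @return Data frame with columns `protein_id`, `r`, `p_global`, `p_adj`.
#' @export
global_pvalues <- function(r_observed, null) {
  if (!length(null$values)) stop_fs("empty null distribution")
  nv <- null$values
  N <- length(nv)
  p <- vapply(r_observed, function(r) (1 + sum(nv >= r)) / (1 + N), numeric(1L))
  data.frame(
    protein_id = names(r_observed) %||% seq_along(r_observed),
    r = unname(r_observed),
    p_global = unname(p),
    p_adj = unname(stats::p.adjust(p, method = "BH")),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Percentile cutoff of the pooled null R distribution
#'
#' Candidate selection thresholds the observed R statistics at a percentile
#' (default 95) of the pooled permutation null, computed with linear
#' interpolation (`stats::quantile()` type 7).
#'
#' @param null an `fs_null`, or a bare numeric vector of null R values.
#' @param percentile percentile in `(0, 100]`.
#' @return The cutoff value.
#' @export
r_cutoff <- function(null, percentile = 95) {
  values <- if (inherits(null, "fs_null")) null$values else null
  if (!length(values)) stop_fs("empty null distribution")
  unname(stats::quantile(values, probs = percentile / 100, type = 7,
                         names = FALSE))
}
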