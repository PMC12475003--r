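#' Kullback-Leibler divergence (bits)
#'
#' Relative entropy `D(P || Q) = sum_x P(x) log2(P(x) / Q(x))`.  Terms with
#' `P(x) = 0` contribute zero (the standard information-theoretic
#' convention); a position with `P(x) > 0` and `Q(x) = 0` makes the
#' divergence infinite.  That infinite branch can never be reached when `Q`
#' is a mixture containing `P` with positive weight, as in the
#' Jensen-Shannon construction.
#'
#' @param p,q probability vectors of equal length.
#' @return Non-negative real (possibly `Inf`), in bits.
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    stop_fs("length mismatch: ", length(p), " vs ", length(q))
  }
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Mixture of two distributions
#'
#' Elementwise average `M(x) = (P(x) + Q(x)) / 2`; the midpoint the
#' Jensen-Shannon distance measures both distributions against.
#'
#' @inheritParams kl_divergence
#' @return Probability vector of the same length.
#' @export
mixture_distribution <- function(p, q) {
  if (length(p) != length(q)) {
    stop_fs("length mismatch: ", length(p), " vs ", length(q))
  }
  (p + q) / 2
}

#' Jensen-Shannon distance (log base 2)
#'
#' Square root of the Jensen-Shannon divergence,
#' `sqrt((D(P || M) + D(Q || M)) / 2)` with `M` the mixture of `P` and `Q`.
#' With base-2 logarithms the result lies in `[0, 1]`: 0 for identical
#' distributions and 1 for distributions with disjoint support.  Unlike the
#' KL divergence it is symmetric, always finite, and a metric, which is what
#' makes it usable as a dissimilarity for the rank-based ANOSIM test.
#'
#' @inheritParams kl_divergence
#' @return Real in `[0, 1]`.
#' @examples
#' jensen_shannon_distance(c(1, 0), c(0, 1))        # 1
#' jensen_shannon_distance(c(0.3, 0.7), c(0.3, 0.7)) # 0
#' @export
jensen_shannon_distance <- function(p, q) {
  m <- mixture_distribution(p, q)
  jsd2 <- (kl_divergence(p, m) + kl_divergence(q, m)) / 2
  sqrt(max(jsd2, 0))
}

# Pluggable distance registry; only "jsd" ships, but alternates can be
# registered without touching the pipeline.
.distance_registry <- new.env(parent = emptyenv())

#' Register or retrieve a profile distance function
#'
#' Distances take two probability vectors and return a non-negative scalar.
#' The default registered distance is `"jsd"`, the Jensen-Shannon distance.
#'
#' @param name distance name.
#' @param fn function of two probability vectors.
#' @return `register_distance()` returns `fn` invisibly;
#'   `distance_function()` returns the registered function.
#' @export
register_distance <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .distance_registry)
  invisible(fn)
}

#' @rdname register_distance
#' @export
distance_function <- function(name = "jsd") {
  if (!exists(name, envir = .distance_registry, inherits = FALSE)) {
    stop_fs(
      "unknown distance ", sQuote(name), "; registered: ",
      paste(ls(.distance_registry), collapse = ", ")
    )
  }
  get(name, envir = .distance_registry, inherits = FALSE)
}

register_distance("jsd", jensen_shannon_distance)

#' Per-protein pairwise sample distance matrix
#'
#' Computes the symmetric matrix of pairwise distances between all valid
#' sample distributions of one protein, across both conditions.  Condition
#' labels are attached for the downstream ANOSIM classification of entries
#' into within- and between-condition pairs.
#'
#' @param profiles an `fs_profileset` from [build_profileset()].
#' @param protein protein identifier.
#' @param distance registered distance name (default `"jsd"`).
#' @return Symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames and a `condition` attribute (one label per row).
#' @export
distance_matrix <- function(profiles, protein, distance = "jsd") {
  idx <- match(protein, dimnames(profiles$profiles)[[1L]])
  if (is.na(idx)) stop_fs("unknown protein ", sQuote(protein))
  if (!profiles$testable[idx]) {
    stop_fs(
      "protein ", sQuote(protein), " is not testable (",
      profiles$reason[idx], "); consult the testable mask"
    )
  }
  dist_fn <- distance_function(distance)
  keep <- which(profiles$valid[idx, ])
  P <- profiles$profiles[idx, keep, , drop = FALSE]
  S <- length(keep)
  d <- matrix(0, S, S)
  ids <- profiles$samples$sample_id[keep]
  dimnames(d) <- list(ids, ids)
  for (a in seq_len(S - 1L)) {
    for (b in (a + 1L):S) {
      d[a, b] <- d[b, a] <- dist_fn(P[1L, a, ], P[1L, b, ])
    }
  }
  attr(d, "condition") <- profiles$samples$condition[keep]
  d
}

#' Distance matrices for all testable proteins
#'
#' @inheritParams distance_matrix
#' @return Named list of [distance_matrix()] results, one per testable
#'   protein; untestable proteins are omitted.
#' @export
pairwise_distance_matrices <- function(profiles, distance = "jsd") {
  ids <- dimnames(profiles$profiles)[[1L]][profiles$testable]
  out <- lapply(ids, function(p) distance_matrix(profiles, p, distance))
  names(out) <- ids
  out
}
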