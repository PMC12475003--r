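# Fixture builders; everything is constructed in code at test time.

# Dissimilarity matrix with constant within- and between-condition entries.
sep_matrix <- function(n_t = 3, n_c = 3, within = 0.1, between = 0.2,
                       labels = c("treatment", "control")) {
  cond <- c(rep(labels[1], n_t), rep(labels[2], n_c))
  n <- n_t + n_c
  d <- matrix(between, n, n)
  d[outer(cond, cond, "==")] <- within
  diag(d) <- 0
  attr(d, "condition") <- cond
  d
}

# Random symmetric dissimilarity matrix with condition labels.
random_dmat <- function(n_t = 3, n_c = 3, labels = c("treatment", "control")) {
  n <- n_t + n_c
  d <- matrix(0, n, n)
  d[lower.tri(d)] <- stats::runif(n * (n - 1) / 2)
  d <- d + t(d)
  attr(d, "condition") <- c(rep(labels[1], n_t), rep(labels[2], n_c))
  d
}

# Design data frame covering n_t + n_c replicates over `fractions`.
make_design_df <- function(n_t = 3, n_c = 3, fractions = paste0("F", 1:4),
                           conditions = c("treatment", "control")) {
  rows <- list()
  for (cond in conditions) {
    n_rep <- if (cond == conditions[1]) n_t else n_c
    for (r in seq_len(n_rep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = paste(cond, r, fractions, sep = "_"),
        condition = cond, replicate = r, fraction = fractions,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Dataset in which every replicate of a condition equals the given
# distribution (times a scale), so that with kernel 1 the condition means
# are exactly those distributions.
dataset_from_means <- function(plus, minus, n_t = 3, n_c = 3,
                               ids = "prot1", scale = 1000,
                               mode = "continuous",
                               conditions = c("treatment", "control"),
                               treatment = "treatment") {
  F_ <- length(plus)
  fractions <- paste0("F", seq_len(F_))
  design <- sample_design(
    make_design_df(n_t, n_c, fractions, conditions),
    treatment = treatment
  )
  tab <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (cond in conditions) {
    n_rep <- if (cond == conditions[1]) n_t else n_c
    p <- if (cond == treatment) plus else minus
    for (r in seq_len(n_rep)) {
      for (k in seq_len(F_)) {
        tab[[paste(cond, r, fractions[k], sep = "_")]] <-
          rep(p[k] * scale, length(ids))
      }
    }
  }
  as_dataset(tab, design, mode = mode)
}

profileset_from_means <- function(plus, minus, ..., beta = 1) {
  ds <- dataset_from_means(plus, minus, ...)
  build_profileset(ds, analysis_config(kernel_size = 1, beta = beta))
}
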