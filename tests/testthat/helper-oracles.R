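# Deliberately naive, loop-based reference implementations used as
# independent oracles.  They share no code with the package internals.

oracle_kl <- function(p, q) {
  p <- unname(p); q <- unname(q)
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log2(p[i] / q[i])
  }
  s
}

oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  sqrt((oracle_kl(p, m) + oracle_kl(q, m)) / 2)
}

# midranks by direct counting: rank = (# strictly smaller) + (ties + 1) / 2
oracle_midrank <- function(v) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }
  out
}

oracle_anosim_r <- function(d, labels) {
  n <- nrow(d)
  vals <- c(); between <- c()
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      vals <- c(vals, d[i, j])
      between <- c(between, labels[i] != labels[j])
    }
  }
  r <- oracle_midrank(vals)
  (mean(r[between]) - mean(r[!between])) / ((n * (n - 1) / 2) / 2)
}

# softmax expectation without the max-subtraction stabilisation
oracle_soft_argmax <- function(w, beta, positions = seq_along(w)) {
  e <- exp(beta * w)
  sum(e / sum(e) * positions)
}

# AUROC by exhaustive pairwise comparison, ties worth 1/2
oracle_auroc <- function(score, positive) {
  ps <- score[positive]; ns <- score[!positive]
  tot <- 0
  for (a in ps) {
    for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(ps) * length(ns))
}

random_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}
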