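test_that("dissimilarity ranks use midranks for ties", {
  m <- matrix(0, 4, 4)
  m[lower.tri(m)] <- c(1, 2, 2, 3, 5, 4)
  m <- m + t(m)
  expect_equal(sort(rank_dissimilarities(m))[1:4], c(1, 2.5, 2.5, 4))

  all_equal <- matrix(1, 4, 4); diag(all_equal) <- 0
  expect_equal(rank_dissimilarities(all_equal), rep(3.5, 6))

  inc <- matrix(0, 4, 4); inc[lower.tri(inc)] <- c(3, 1, 6, 2, 4, 5)
  inc <- inc + t(inc)
  expect_equal(sort(rank_dissimilarities(inc)), 1:6)
})

test_that("ANOSIM R reaches its extremes and hand-computed values", {
  expect_equal(anosim_r(sep_matrix()), 1)

  flat <- matrix(0.5, 6, 6); diag(flat) <- 0
  expect_equal(anosim_r(flat, c(rep("a", 3), rep("b", 3))), 0)

  # within ranks {1,2,3} and {7,8,9}; between ranks {4,5,6,10..15}
  d <- matrix(0, 6, 6)
  within_a <- rbind(c(2, 1), c(3, 1), c(3, 2))
  within_b <- rbind(c(5, 4), c(6, 4), c(6, 5))
  between <- rbind(c(4, 1), c(4, 2), c(4, 3), c(5, 1), c(5, 2), c(5, 3),
                   c(6, 1), c(6, 2), c(6, 3))
  d[within_a] <- 1:3; d[within_b] <- 7:9
  d[between] <- c(4, 5, 6, 10, 11, 12, 13, 14, 15)
  d <- d + t(d)
  expect_equal(anosim_r(d, c(rep("a", 3), rep("b", 3))), (10 - 5) / 7.5)

  expect_error(anosim_r(sep_matrix(), c("a", "a", "a", "a", "a", "b")),
               "at least 2 samples")
})

test_that("R is rank-based: invariant under strictly increasing transforms", {
  set.seed(11)
  for (i in 1:50) {
    d <- random_dmat(sample(2:4, 1), sample(2:4, 1))
    labels <- attr(d, "condition")
    r0 <- anosim_r(d, labels)
    expect_gte(r0, -1); expect_lte(r0, 1)
    expect_equal(anosim_r(exp(3 * d) - 1, labels), r0, tolerance = 1e-12)
    expect_equal(anosim_r(d^3, labels), r0, tolerance = 1e-12)
    expect_equal(anosim_r(d, labels), oracle_anosim_r(d, labels),
                 tolerance = 1e-12)
  }
})

test_that("R agrees with an independent community-ecology implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  for (i in 1:20) {
    n_t <- sample(2:4, 1); n_c <- sample(2:4, 1)
    d <- random_dmat(n_t, n_c)
    grouping <- factor(attr(d, "condition"))
    veg <- suppressWarnings(
      vegan::anosim(stats::as.dist(d), grouping, permutations = 0)
    )
    expect_equal(anosim_r(d, attr(d, "condition")), unname(veg$statistic),
                 tolerance = 1e-10)
  }
})

test_that("label-assignment enumeration matches closed-form counts", {
  a33 <- enumerate_label_assignments(3, 3)
  expect_length(a33, 10)
  expect_identical(a33[[1]], 1:3)  # identity first
  expect_equal(length(unique(lapply(a33, sort))), 10)

  expect_length(enumerate_label_assignments(2, 2), 3)
  expect_length(enumerate_label_assignments(3, 2), choose(5, 3))

  for (n_t in 2:4) {
    for (n_c in 2:4) {
      expected <- if (n_t == n_c) {
        factorial(2 * n_t) / (2 * factorial(n_t)^2)
      } else {
        choose(n_t + n_c, n_t)
      }
      expect_length(enumerate_label_assignments(n_t, n_c), expected)
      expect_equal(n_label_assignments(n_t, n_c), expected)
    }
  }
})

test_that("local exact p-values include the identity and have a 3v3 floor of 0.1", {
  d <- sep_matrix()
  expect_equal(local_permutation_pvalue(d), 0.1)
  expect_gt(local_permutation_pvalue(d), 0.05)

  flat <- matrix(0.5, 6, 6); diag(flat) <- 0
  attr(flat, "condition") <- attr(d, "condition")
  expect_equal(local_permutation_pvalue(flat), 1)

  set.seed(13)
  for (i in 1:20) {
    dm <- random_dmat(3, 3)
    p <- local_permutation_pvalue(dm)
    expect_gte(p, 0.1)
    expect_lte(p, 1)
  }
})

test_that("Monte-Carlo local p-values are seeded and close to exact", {
  d <- random_dmat(3, 3)
  p1 <- local_permutation_pvalue(d, mode = "monte_carlo",
                                 n_monte_carlo = 499, seed = 7)
  p2 <- local_permutation_pvalue(d, mode = "monte_carlo",
                                 n_monte_carlo = 499, seed = 7)
  expect_identical(p1, p2)
  p_exact <- local_permutation_pvalue(d)
  expect_lt(abs(p1 - p_exact), 0.1)
})

test_that("pooled null has the expected size and zero mean over enumerations", {
  set.seed(14)
  dmats <- list(a = random_dmat(3, 3), b = random_dmat(3, 3))
  cfg <- analysis_config(seed = 1)
  null <- global_null_distribution(dmats, cfg)
  expect_length(null$values, 18)  # 2 x (10 - 1), identity excluded

  cfg_id <- analysis_config(seed = 1, include_identity_in_null = TRUE)
  null_id <- global_null_distribution(dmats, cfg_id)
  expect_length(null_id$values, 20)

  # complete enumeration with identity averages to zero exactly
  for (i in 1:10) {
    dm <- random_dmat(sample(2:4, 1), sample(2:4, 1))
    n1 <- global_null_distribution(list(x = dm), cfg_id)
    expect_lt(abs(mean(n1$values)), 1e-12)
  }
})

test_that("large designs fall back to seeded Monte-Carlo pooling", {
  set.seed(15)
  dm <- random_dmat(8, 8)  # 6435 distinct assignments
  cfg <- analysis_config(seed = 5, exact_limit = 100, n_monte_carlo = 50)
  null <- global_null_distribution(list(x = dm), cfg)
  expect_equal(unname(null$mode), "monte_carlo")
  expect_length(null$values, 50)
  null2 <- global_null_distribution(list(x = dm), cfg)
  expect_identical(null$values, null2$values)
})

test_that("global p-values use the add-one estimator and BH adjustment", {
  null <- structure(list(values = seq(-0.85, 0.85, by = 0.1)), class = "fs_null")
  expect_length(null$values, 18)
  gp <- global_pvalues(c(top = 0.99), null)
  expect_equal(gp$p_global, 1 / 19)

  gp_low <- global_pvalues(c(worst = -0.99), null)
  expect_equal(gp_low$p_global, 1)

  expect_equal(
    stats::p.adjust(c(0.005, 0.01, 0.03, 0.04), method = "BH"),
    c(0.02, 0.02, 0.04, 0.04)
  )
  expect_error(global_pvalues(0.5, structure(list(values = numeric(0)),
                                             class = "fs_null")),
               "empty null")
})

test_that("the R cutoff is an interpolated percentile and monotone", {
  expect_equal(r_cutoff(c(-1, 0, 0, 0, 1), 100), 1)
  null19 <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(r_cutoff(null19, 95), 0.81)
  cuts <- vapply(c(10, 50, 90, 95, 100), function(p) r_cutoff(null19, p),
                 numeric(1))
  expect_true(all(diff(cuts) >= 0))
  expect_error(r_cutoff(numeric(0), 95), "empty null")
})
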