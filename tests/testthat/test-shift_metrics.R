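test_that("position-wise relative entropy decomposes the KL divergence", {
  p <- random_simplex(8)
  expect_equal(positionwise_relative_entropy(p, p), rep(0, 8))
  expect_equal(positionwise_relative_entropy(c(1, 0), c(0.5, 0.5)), c(1, 0))
  expect_error(positionwise_relative_entropy(c(0.5, 0.5), c(1, 0)),
               "zero mass")

  set.seed(21)
  for (i in 1:50) {
    a <- random_simplex(9); b <- random_simplex(9)
    m <- mixture_distribution(a, b)
    w <- positionwise_relative_entropy(a, m)
    expect_equal(sum(w), kl_divergence(a, m), tolerance = 1e-12)
  }
})

test_that("soft-argmax interpolates between mean position and hard argmax", {
  expect_equal(soft_argmax_position(rep(0, 7), 1), 4)  # (F + 1) / 2
  expect_equal(soft_argmax_position(c(0, 1), 1), 1.7310585786,
               tolerance = 1e-9)

  w <- c(0.1, 0.4, 0.2, 0.3, 1.0, 0.6)
  expect_equal(soft_argmax_position(w, 1000), 5, tolerance = 1e-6)

  # shift invariance and agreement with the unstabilised oracle
  set.seed(22)
  for (i in 1:50) {
    w <- runif(10)
    b <- runif(1, 0.5, 20)
    s <- soft_argmax_position(w, b)
    expect_equal(s, oracle_soft_argmax(w, b), tolerance = 1e-10)
    expect_equal(soft_argmax_position(w + 3.7, b), s, tolerance = 1e-10)
    expect_gte(s, 1); expect_lte(s, 10)
  }

  # strictly monotone in beta for a two-point score
  betas <- c(0.5, 1, 2, 5, 10)
  s2 <- vapply(betas, function(b) soft_argmax_position(c(0, 1), b), numeric(1))
  expect_true(all(diff(s2) > 0))

  expect_error(soft_argmax_position(c(0, 1), beta = -1), "positive")
})

test_that("effect-size JSD equals the distance module on the stored means", {
  plus <- c(0.05, 0.15, 0.6, 0.15, 0.05)
  minus <- c(0.6, 0.2, 0.1, 0.05, 0.05)
  ps <- profileset_from_means(plus, minus)
  expect_equal(effect_size_jsd(ps, "prot1"),
               jensen_shannon_distance(plus, minus), tolerance = 1e-12)

  same <- profileset_from_means(plus, plus)
  expect_equal(effect_size_jsd(same, "prot1"), 0)

  disjoint <- profileset_from_means(c(1, 0, 0, 0), c(0, 0, 1, 0))
  expect_equal(effect_size_jsd(disjoint, "prot1"), 1)
})

test_that("relative fraction shift recovers point-mass shifts with sign", {
  F_ <- 8
  plus <- numeric(F_); plus[2] <- 1
  minus <- numeric(F_); minus[6] <- 1
  ps <- profileset_from_means(plus, minus)
  rfs <- relative_fraction_shift(ps, "prot1", beta = 1000)
  expect_equal(rfs$rps, -4, tolerance = 1e-6)
  expect_equal(rfs$S_plus, 2, tolerance = 1e-6)
  expect_equal(rfs$S_minus, 6, tolerance = 1e-6)

  # identical means carry no shift
  same <- profileset_from_means(plus, plus)
  expect_equal(relative_fraction_shift(same, "prot1", beta = 5)$rps, 0)

  # swapping which condition is the treatment negates the shift
  swapped <- profileset_from_means(minus, plus)
  expect_equal(relative_fraction_shift(swapped, "prot1", beta = 1000)$rps, 4,
               tolerance = 1e-6)
})

test_that("relative distribution change is the entropy difference in bits", {
  uniform4 <- rep(0.25, 4)
  point <- c(1, 0, 0, 0)
  ps <- profileset_from_means(uniform4, point)
  expect_equal(relative_distribution_change(ps, "prot1"), 2)
  swapped <- profileset_from_means(point, uniform4)
  expect_equal(relative_distribution_change(swapped, "prot1"), -2)
  same <- profileset_from_means(uniform4, uniform4)
  expect_equal(relative_distribution_change(same, "prot1"), 0)
})

test_that("mean within-condition distance matches the brute-force mean", {
  p <- c(0.2, 0.3, 0.5)
  ps <- profileset_from_means(p, p)
  expect_equal(mean_within_jsd(ps, "prot1", "treatment"), 0)

  set.seed(23)
  sim <- simulate_dataset(simulation_config(n_proteins = 3, noise = 0.3,
                                            seed = 31))
  psn <- build_profileset(sim$dataset, analysis_config())
  for (cond in c("treatment", "control")) {
    keep <- which(psn$samples$condition == cond)
    vals <- c()
    for (a in keep) {
      for (b in keep) {
        if (a < b) vals <- c(vals, oracle_jsd(psn$profiles[2, a, ],
                                              psn$profiles[2, b, ]))
      }
    }
    expect_equal(mean_within_jsd(psn, "P0002", cond), mean(vals),
                 tolerance = 1e-12)
  }
})

test_that("categorical axes keep entropy metrics but not positional ones", {
  plus <- c(0.7, 0.2, 0.1); minus <- c(0.1, 0.2, 0.7)
  ps <- profileset_from_means(plus, minus, mode = "categorical")
  expect_error(relative_fraction_shift(ps, "prot1"), "categorical")
  expect_equal(effect_size_jsd(ps, "prot1"),
               jensen_shannon_distance(plus, minus))
  sm <- shift_metrics(ps, analysis_config(kernel_size = 1))
  expect_true(is.na(sm$relative_fraction_shift))
  expect_false(is.na(sm$relative_distribution_change))
  expect_false(is.na(sm$effect_jsd))
})

test_that("shift metrics are antisymmetric under condition swap, JSD symmetric", {
  set.seed(24)
  for (i in 1:10) {
    plus <- random_simplex(6); minus <- random_simplex(6)
    a <- profileset_from_means(plus, minus)
    b <- profileset_from_means(minus, plus)
    expect_equal(effect_size_jsd(a, "prot1"), effect_size_jsd(b, "prot1"),
                 tolerance = 1e-12)
    expect_equal(relative_fraction_shift(a, "prot1", beta = 2)$rps,
                 -relative_fraction_shift(b, "prot1", beta = 2)$rps,
                 tolerance = 1e-12)
    expect_equal(relative_distribution_change(a, "prot1"),
                 -relative_distribution_change(b, "prot1"),
                 tolerance = 1e-12)
  }
})
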