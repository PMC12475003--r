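test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_proteins = 10, missing_prob = 0.1, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_dataset(simulation_config(n_proteins = 10,
                                           missing_prob = 0.1, seed = 100))
  expect_false(identical(a$dataset$intensities, c_$dataset$intensities))
})

test_that("the truth table has one record per protein with coherent fields", {
  sim <- simulate_dataset(simulation_config(n_proteins = 25,
                                            shifted_fraction = 0.4, seed = 2))
  expect_equal(nrow(sim$truth), 25)
  expect_equal(sum(sim$truth$shifted), 10)
  expect_true(all(sim$truth$shift_distance[!sim$truth$shifted] == 0))
  expect_true(all(sim$truth$shift_distance[sim$truth$shifted] == -4))
})

test_that("no-shift zero-noise data yield null statistics", {
  sim <- simulate_dataset(simulation_config(n_proteins = 10,
                                            shifted_fraction = 0, noise = 0,
                                            seed = 4))
  fit <- run_analysis(sim$dataset, analysis_config(seed = 4))
  expect_true(all(fit$results$effect_jsd < 1e-9))
  expect_true(all(fit$results$anosim_r <= 0))
})

test_that("an out-of-range shift distance is a configuration error", {
  expect_error(
    simulate_dataset(simulation_config(n_fractions = 10, shift_distance = -9)),
    "shift_distance"
  )
  expect_error(simulation_config(shift_mass = 0), "shift_mass")
  expect_error(simulation_config(noise = -1), "noise")
})

test_that("missingness and partial shifts behave as configured", {
  sim <- simulate_dataset(simulation_config(n_proteins = 200,
                                            missing_prob = 0.2, seed = 5))
  arr <- sim$dataset$intensities
  # missing whole (protein, sample) profiles, at roughly the configured rate
  miss <- apply(arr, c(1, 2), function(v) all(is.na(v)))
  expect_gt(mean(miss), 0.12); expect_lt(mean(miss), 0.28)
  expect_true(all(apply(arr, c(1, 2), function(v) all(is.na(v)) || !anyNA(v))))

  full <- simulate_dataset(simulation_config(n_proteins = 40, noise = 0,
                                             shift_mass = 1, seed = 6))
  part <- simulate_dataset(simulation_config(n_proteins = 40, noise = 0,
                                             shift_mass = 0.3, seed = 6))
  f_full <- run_analysis(full$dataset, analysis_config(seed = 6))
  f_part <- run_analysis(part$dataset, analysis_config(seed = 6))
  jsd_full <- f_full$results$effect_jsd[f_full$results$protein_id %in%
                                          full$truth$protein_id[full$truth$shifted]]
  jsd_part <- f_part$results$effect_jsd[f_part$results$protein_id %in%
                                          part$truth$protein_id[part$truth$shifted]]
  expect_gt(mean(jsd_full), mean(jsd_part))
})

test_that("broadening-only scenarios raise entropy without moving the peak", {
  sim <- simulate_dataset(simulation_config(
    n_proteins = 30, shifted_fraction = 0.5, shift_distance = 0,
    broadening = 2.5, noise = 0, seed = 8
  ))
  fit <- run_analysis(sim$dataset, analysis_config(seed = 8))
  df <- merge(as.data.frame(fit$results), sim$truth, by = "protein_id")
  sh <- df[df$shifted, ]
  expect_true(all(sh$relative_distribution_change > 0))
  expect_true(all(abs(sh$relative_fraction_shift) < 0.75))
})

test_that("ranking benchmark matches the pairwise-counting oracle", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    rank_vec <- sample(n)
    truth <- data.frame(
      protein_id = sprintf("p%02d", 1:n),
      shifted = runif(n) < 0.4,
      stringsAsFactors = FALSE
    )
    if (!any(truth$shifted)) truth$shifted[1] <- TRUE
    if (all(truth$shifted)) truth$shifted[1] <- FALSE
    ranked <- data.frame(protein_id = truth$protein_id, rank = rank_vec,
                         stringsAsFactors = FALSE)
    b <- benchmark_ranking(ranked, truth)
    expect_equal(b$auroc, oracle_auroc(-rank_vec, truth$shifted),
                 tolerance = 1e-12)
  }
})

test_that("random labels give chance-level AUROC, degenerate truth flags", {
  set.seed(42)
  n <- 400
  ranked <- data.frame(protein_id = sprintf("p%03d", 1:n), rank = sample(n),
                       stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = ranked$protein_id,
                      shifted = runif(n) < 0.5, stringsAsFactors = FALSE)
  b <- benchmark_ranking(ranked, truth)
  expect_lt(abs(b$auroc - 0.5), 0.1)

  all_pos <- truth; all_pos$shifted <- TRUE
  expect_true(benchmark_ranking(ranked, all_pos)$degenerate)
})
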