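#' Simulation configuration
#'
#' Parameters of the synthetic fractionation-dataset generator.  Defaults
#' emulate a typical density-gradient experiment: 20 fractions, three
#' replicates per condition, localized bell-shaped peaks, a minority of
#' proteins shifting leftwards (towards lighter fractions) after treatment,
#' and mild compositional replicate noise.
#'
#' @param n_proteins number of proteins to generate.
#' @param n_fractions number of fractions `F`.
#' @param n_treatment,n_control replicates per condition.
#' @param shifted_fraction fraction of proteins given a true shift.
#' @param shift_distance signed shift distance in fractions (negative =
#'   leftward).
#' @param shift_mass portion `(0, 1]` of a shifted protein's mass that
#'   moves (partial shifts emulate complexes of which only a subpopulation
#'   redistributes).
#' @param peak_width Gaussian peak standard deviation, in fractions.
#' @param broadening multiplicative width factor for the shifted peak in
#'   the treated condition (`> 1` broadens, `< 1` sharpens).
#' @param noise replicate noise level: replicate distributions are Dirichlet
#'   draws with concentration `mean / noise`, so larger values mean noisier
#'   replicates and `0` means replicates equal their condition mean exactly.
#' @param missing_prob probability that a whole (protein, sample)
#'   measurement is missing.
#' @param intensity_scale total-intensity scale used to convert probability
#'   profiles back to intensities.
#' @param seed integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 100L,
                              n_fractions = 20L,
                              n_treatment = 3L,
                              n_control = 3L,
                              shifted_fraction = 0.2,
                              shift_distance = -4,
                              shift_mass = 1,
                              peak_width = 1,
                              broadening = 1,
                              noise = 0.02,
                              missing_prob = 0,
                              intensity_scale = 1e7,
                              seed = 1L) {
  if (n_proteins < 1L || n_fractions < 2L) {
    stop_fs("n_proteins must be positive and n_fractions at least 2")
  }
  if (n_treatment < 2L || n_control < 2L) {
    stop_fs("at least 2 replicates per condition are required")
  }
  if (shift_mass <= 0 || shift_mass > 1) stop_fs("shift_mass must be in (0, 1]")
  if (peak_width <= 0) stop_fs("peak_width must be positive")
  if (noise < 0) stop_fs("noise must be non-negative")
  if (missing_prob < 0 || missing_prob >= 1) {
    stop_fs("missing_prob must be in [0, 1)")
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_fractions = as.integer(n_fractions),
      n_treatment = as.integer(n_treatment),
      n_control = as.integer(n_control),
      shifted_fraction = shifted_fraction,
      shift_distance = shift_distance,
      shift_mass = shift_mass,
      peak_width = peak_width,
      broadening = broadening,
      noise = noise,
      missing_prob = missing_prob,
      intensity_scale = intensity_scale,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Discretized Gaussian peak on fractions 1..F, clipped to the measured
# range and renormalized.
.peak_profile <- function(center, width, F_) {
  p <- stats::dnorm(seq_len(F_), mean = center, sd = width)
  p / sum(p)
}

# Dirichlet perturbation of a mean distribution; noise = 0 reproduces the
# mean exactly (infinite concentration limit).
.simplex_noise <- function(mean_p, noise) {
  if (noise == 0) return(mean_p)
  g <- stats::rgamma(length(mean_p), shape = mean_p / noise)
  s <- sum(g)
  if (s <= 0) mean_p else g / s
}

#' Simulate a fractionation dataset with known ground truth
#'
#' Each protein gets a bell-shaped base profile at a random in-range peak
#' position.  For shifted proteins the treated condition mean moves a
#' `shift_mass` portion of the mass by `shift_distance` fractions (with
#' optional peak broadening); control means equal the base profile.
#' Replicates are compositional (Dirichlet) perturbations of their
#' condition mean, rescaled to intensities with log-normal total-intensity
#' variation.  Peak positions are drawn so that both the base and the
#' shifted peak fit inside the fraction range; a `shift_distance` that
#' leaves no admissible positions is a configuration error.
#'
#' @param config a [simulation_config()].
#' @return A list of class `fs_simulation` with elements `dataset` (an
#'   `fs_dataset`), `truth` (data frame: `protein_id`, `shifted`,
#'   `shift_distance`, `shift_mass`, `broadening`, `peak_center`) and the
#'   `config`.  Given the same config (including seed), output is
#'   bit-identical.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  F_ <- config$n_fractions
  sigma <- config$peak_width
  delta <- if (config$shifted_fraction > 0) config$shift_distance else 0
  margin <- 2 * sigma * max(1, config$broadening)
  lo <- 1 + margin + max(0, -delta)
  hi <- F_ - margin - max(0, delta)
  if (lo >= hi) {
    stop_fs(
      "shift_distance = ", config$shift_distance,
      " leaves no admissible peak positions for n_fractions = ", F_,
      " and peak_width = ", sigma
    )
  }

  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  fractions <- sprintf("F%02d", seq_len(F_))
  conds <- c("treatment", "control")
  reps <- list(
    treatment = seq_len(config$n_treatment),
    control = seq_len(config$n_control)
  )

  sim <- with_seed(config$seed, {
    n_shift <- round(n * config$shifted_fraction)
    shifted <- logical(n)
    if (n_shift > 0) shifted[sample.int(n, n_shift)] <- TRUE
    centers <- stats::runif(n, lo, hi)

    intensities <- list()
    for (i in seq_len(n)) {
      base <- .peak_profile(centers[i], sigma, F_)
      treated_mean <- if (shifted[i]) {
        moved <- .peak_profile(centers[i] + config$shift_distance,
                               sigma * config$broadening, F_)
        (1 - config$shift_mass) * base + config$shift_mass * moved
      } else {
        base
      }
      row <- numeric(0)
      for (cond in conds) {
        mean_p <- if (cond == "treatment") treated_mean else base
        for (r in reps[[cond]]) {
          if (config$missing_prob > 0 &&
              stats::runif(1) < config$missing_prob) {
            row <- c(row, rep(NA_real_, F_))
          } else {
            p <- .simplex_noise(mean_p, config$noise)
            # total-intensity variation is replicate noise too: exact copies
            # at noise = 0
            total <- config$intensity_scale *
              (if (config$noise > 0) exp(stats::rnorm(1, 0, 0.25)) else 1)
            row <- c(row, p * total)
          }
        }
      }
      intensities[[i]] <- row
    }
    list(shifted = shifted, centers = centers,
         mat = do.call(rbind, intensities))
  })

  cols <- character(0)
  entries <- list()
  for (cond in conds) {
    for (r in reps[[cond]]) {
      cols <- c(cols, paste(cond, r, fractions, sep = "_"))
      entries[[length(entries) + 1L]] <- data.frame(
        sample = paste(cond, r, fractions, sep = "_"),
        condition = cond, replicate = r, fraction = fractions,
        stringsAsFactors = FALSE
      )
    }
  }
  design <- sample_design(do.call(rbind, entries), treatment = "treatment")

  table <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  table[cols] <- as.data.frame(sim$mat)
  dataset <- as_dataset(table, design, mode = "continuous")

  truth <- data.frame(
    protein_id = ids,
    shifted = sim$shifted,
    shift_distance = ifelse(sim$shifted, config$shift_distance, 0),
    shift_mass = ifelse(sim$shifted, config$shift_mass, 0),
    broadening = ifelse(sim$shifted, config$broadening, 1),
    peak_center = sim$centers,
    stringsAsFactors = FALSE
  )

  structure(list(dataset = dataset, truth = truth, config = config),
            class = "fs_simulation")
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Writes `intensities.tsv`, `design.tsv` and `truth.tsv` to a directory, in
#' exactly the formats [read_intensity_table()] and [read_design()] consume.
#'
#' @param sim an `fs_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$dataset
  arr <- ds$intensities
  design <- ds$design

  tab <- data.frame(protein_id = ds$proteins, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(design))) {
    sid <- paste(design$condition[k], design$replicate[k], sep = ".")
    tab[[design$sample[k]]] <- arr[, sid, design$fraction[k]]
  }
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], function(x) {
    ifelse(is.na(x), "", formatC(x, digits = 15, format = "g"))
  })
  utils::write.table(tab, file.path(dir, "intensities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(design), file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Benchmark a ranking against simulation ground truth
#'
#' Evaluates how well the ranking places truly shifted proteins at the top:
#' AUROC of the rank ordering against the shifted/unshifted labels
#' (midrank-tie handling; untestable proteins are placed jointly below all
#' ranked proteins) and the median rank of each group.
#'
#' @param ranked an `fs_ranked` table from [rank_proteins()] or
#'   [run_analysis()].
#' @param truth truth table from [simulate_dataset()].
#' @return List with `auroc`, `median_rank_shifted`,
#'   `median_rank_unshifted`, `n_shifted`, `n_unshifted` and `degenerate`
#'   (`TRUE`, with `auroc = NA`, when the truth has only one class).
#' @export
benchmark_ranking <- function(ranked, truth) {
  m <- merge(ranked[, c("protein_id", "rank")], truth[, c("protein_id", "shifted")],
             by = "protein_id")
  worst <- max(m$rank, na.rm = TRUE) + 1L
  eff_rank <- ifelse(is.na(m$rank), worst, m$rank)
  pos <- m$shifted
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    return(list(auroc = NA_real_, median_rank_shifted = NA_real_,
                median_rank_unshifted = NA_real_, n_shifted = n_pos,
                n_unshifted = n_neg, degenerate = TRUE))
  }
  score <- -eff_rank  # higher score = stronger candidate
  r <- rank(score, ties.method = "average")
  auroc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(
    auroc = auroc,
    median_rank_shifted = stats::median(eff_rank[pos]),
    median_rank_unshifted = stats::median(eff_rank[!pos]),
    n_shifted = n_pos,
    n_unshifted = n_neg,
    degenerate = FALSE
  )
}
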