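#' Simulation parameters for a synthetic flanker-task EEG cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator.
#' Defaults encode the study conditions the generator emulates: 60 trials per
#' congruency condition, 500 Hz sampling, 3-s epochs from -2000 to +1000 ms
#' around stimulus onset, occipital alpha with a subject-specific peak
#' frequency drawn uniformly from `alpha_freq_range`, and a per-group target
#' Spearman correlation between true single-trial alpha power and RT
#' (`coupling_rho`): positive (+0.10) in healthy controls (HC), near zero
#' (-0.03) in mild cognitive impairment (MCI).
#'
#' Per-trial alpha amplitude is lognormal(`alpha_amp_meanlog`,
#' `alpha_amp_sdlog`) in microvolts; each channel additionally carries
#' independent 1/f^`noise_exponent` background noise scaled to `noise_amp`
#' microvolts RMS. RT is truncated normal (resampled below `rt_min`) with
#' per-condition mean/SD (498/55 ms congruent, 538/58 ms incongruent).
#' Response errors are Bernoulli with per-group, per-condition rates.
#'
#' @param n_per_group subjects per group (HC and MCI).
#' @param trials_per_condition trials per congruency condition (>= 4).
#' @param fs sampling rate, Hz.
#' @param epoch_window epoch limits in ms relative to stimulus onset.
#' @param channels channel names; must contain Oz, O1, O2 exactly once each.
#' @param alpha_freq_range range (Hz) the subject alpha peak is drawn from.
#' @param alpha_amp_meanlog,alpha_amp_sdlog lognormal parameters of the
#'   per-trial alpha amplitude (microvolts).
#' @param occipital_gain,other_gain alpha amplitude gain on occipital and
#'   non-occipital channels (the attenuated copy on other channels keeps
#'   average re-referencing non-degenerate).
#' @param noise_exponent spectral slope of the 1/f background.
#' @param noise_amp RMS amplitude (microvolts) of the background noise.
#' @param coupling_rho named vector (HC, MCI) or 2x2 matrix
#'   (rows HC/MCI, columns congruent/incongruent) of target Spearman
#'   correlations between true alpha power and RT; each in (-1, 1).
#' @param rt_mean,rt_sd named per-condition RT mean and SD, ms.
#' @param rt_min lower RT truncation bound, ms (resampled, not clipped).
#' @param error_rate 2x2 matrix (rows HC/MCI, columns
#'   congruent/incongruent) of incorrect-response probabilities.
#' @param seed integer RNG seed for the cohort.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_per_group = 28,
                       trials_per_condition = 60,
                       fs = 500,
                       epoch_window = c(-2000, 1000),
                       channels = c("Fz", "Cz", "Pz", "P3", "P4",
                                    "O1", "Oz", "O2"),
                       alpha_freq_range = c(9, 11),
                       alpha_amp_meanlog = log(1),
                       alpha_amp_sdlog = 0.4,
                       occipital_gain = 1,
                       other_gain = 0.3,
                       noise_exponent = 1,
                       noise_amp = 1,
                       coupling_rho = c(HC = 0.10, MCI = -0.03),
                       rt_mean = c(congruent = 498, incongruent = 538),
                       rt_sd = c(congruent = 55, incongruent = 58),
                       rt_min = 150,
                       error_rate = matrix(c(0.06, 0.07, 0.05, 0.10), 2, 2,
                                           byrow = TRUE,
                                           dimnames = list(c("HC", "MCI"),
                                                           c("congruent",
                                                             "incongruent"))),
                       seed = 1L) {
  stopifnot(n_per_group >= 1, trials_per_condition >= 4, fs > 0,
            length(epoch_window) == 2, epoch_window[1] < epoch_window[2])
  for (ch in c("Oz", "O1", "O2"))
    if (sum(channels == ch) != 1L)
      stop("channel list must contain ", ch, " exactly once")
  rho <- coupling_matrix(coupling_rho)
  if (any(abs(rho) >= 1)) stop("coupling_rho must lie in (-1, 1)")
  rt_mean <- cond_vec(rt_mean, "rt_mean")
  rt_sd <- cond_vec(rt_sd, "rt_sd")
  if (any(rt_mean <= 0) || any(rt_sd <= 0)) stop("rt_mean and rt_sd must be > 0")
  stopifnot(all(dim(error_rate) == c(2, 2)),
            all(error_rate >= 0 & error_rate < 1))
  dimnames(error_rate) <- list(c("HC", "MCI"), c("congruent", "incongruent"))
  p <- list(n_per_group = as.integer(n_per_group),
            trials_per_condition = as.integer(trials_per_condition),
            fs = fs, epoch_window = epoch_window, channels = channels,
            alpha_freq_range = alpha_freq_range,
            alpha_amp_meanlog = alpha_amp_meanlog,
            alpha_amp_sdlog = alpha_amp_sdlog,
            occipital_gain = occipital_gain, other_gain = other_gain,
            noise_exponent = noise_exponent, noise_amp = noise_amp,
            coupling_rho = rho, rt_mean = rt_mean, rt_sd = rt_sd,
            rt_min = rt_min, error_rate = error_rate,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

# expand scalar / per-group vector / full matrix into a 2x2 group x condition
# matrix with rows HC, MCI and columns congruent, incongruent
coupling_matrix <- function(rho) {
  grp <- c("HC", "MCI"); cnd <- c("congruent", "incongruent")
  if (is.matrix(rho)) {
    stopifnot(all(dim(rho) == c(2, 2)))
    m <- rho
  } else if (length(rho) == 2) {
    if (!is.null(names(rho))) rho <- rho[grp]
    m <- matrix(rep(as.numeric(rho), 2), 2, 2)
  } else if (length(rho) == 1) {
    m <- matrix(rho, 2, 2)
  } else stop("coupling_rho must be length 1, 2, or a 2x2 matrix")
  dimnames(m) <- list(grp, cnd)
  m
}

cond_vec <- function(x, what) {
  cnd <- c("congruent", "incongruent")
  if (length(x) == 1) x <- c(x, x)
  if (!is.null(names(x)) && all(cnd %in% names(x))) x <- x[cnd]
  if (length(x) != 2) stop(what, " must have one value per condition")
  stats::setNames(as.numeric(x), cnd)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic flanker-EEG cohort parameters\n")
  cat(sprintf("  %d subjects/group, %d trials/condition, fs = %g Hz\n",
              x$n_per_group, x$trials_per_condition, x$fs))
  cat(sprintf("  epoch %d..%d ms, %d channels\n",
              x$epoch_window[1], x$epoch_window[2], length(x$channels)))
  cat("  coupling rho (group x condition):\n")
  print(round(x$coupling_rho, 3))
  invisible(x)
}

# deterministic fan-out of one cohort seed into per-subject streams; keeps
# children inside the 32-bit range set.seed() accepts
child_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 69069 + 12345 +
    101 * as.numeric(index)
  as.integer(s %% 2147483647)
}
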