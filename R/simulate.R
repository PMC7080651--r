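#' Simulate one subject's epoched flanker-task EEG
#'
#' Generates a trials x channels x samples cube with a controlled rank
#' correlation between true single-trial prestimulus alpha power and RT.
#' For each trial a standard-normal latent pair (u, v) is drawn with Pearson
#' correlation r = 2 sin(pi * rho / 6), the Gaussian-copula inverse of the
#' target Spearman rho; u maps through the lognormal quantile to the trial's
#' alpha amplitude a_i and v maps through the normal quantile to its RT
#' (resampled jointly while RT < rt_min so the copula's rank structure is
#' preserved). The trial's signal is a_i * cos(2 pi f t + phi_i) over the
#' whole epoch (full gain on Oz/O1/O2, attenuated elsewhere) plus
#' channel-independent 1/f noise. Since Spearman correlation is invariant to
#' the square on positive amplitudes, the alpha-power-vs-RT rank correlation
#' equals the amplitude-vs-RT one by construction.
#'
#' @param params a [sim_params()] object.
#' @param group `"HC"` or `"MCI"` (selects coupling and error rates).
#' @param subject_seed integer seed for this subject's RNG stream.
#' @param subject_id identifier stored in the trial table.
#' @return an `epoched_recording`: list with `data` (trials x channels x
#'   samples, microvolts), `fs`, `times` (ms), `channel_names`, and
#'   `trial_table` (trial_id, condition, rt, correct, artifact,
#'   true_alpha_amp, true_alpha_power).
#' @export
simulate_subject <- function(params, group, subject_seed = params$seed,
                             subject_id = "s1") {
  stopifnot(inherits(params, "sim_params"))
  if (!group %in% c("HC", "MCI")) stop("group must be 'HC' or 'MCI'")
  set.seed(as.integer(subject_seed))

  fs <- params$fs
  times <- seq(params$epoch_window[1], params$epoch_window[2], by = 1000 / fs)
  n_samp <- length(times)
  chans <- params$channels
  n_chan <- length(chans)
  n_per <- params$trials_per_condition
  conds <- c("congruent", "incongruent")

  f_alpha <- stats::runif(1, params$alpha_freq_range[1],
                          params$alpha_freq_range[2])

  amp <- rt <- numeric(0); cond <- character(0); correct <- logical(0)
  for (cn in conds) {
    rho <- params$coupling_rho[group, cn]
    uv <- copula_pairs(n_per, rho, params$rt_mean[cn], params$rt_sd[cn],
                       params$rt_min)
    a <- stats::qlnorm(stats::pnorm(uv$u), params$alpha_amp_meanlog,
                       params$alpha_amp_sdlog)
    amp <- c(amp, a)
    rt <- c(rt, uv$rt)
    cond <- c(cond, rep(cn, n_per))
    correct <- c(correct,
                 stats::runif(n_per) >= params$error_rate[group, cn])
  }
  ord <- sample.int(2 * n_per)            # randomized trial order
  amp <- amp[ord]; rt <- rt[ord]; cond <- cond[ord]; correct <- correct[ord]
  n_tr <- 2 * n_per

  phi <- stats::runif(n_tr, 0, 2 * pi)
  omega_t <- 2 * pi * f_alpha * times / 1000
  # W[i, s] = amp_i * cos(omega_t_s + phi_i), via two outer products
  wave <- (amp * cos(phi)) %o% cos(omega_t) - (amp * sin(phi)) %o% sin(omega_t)
  gain <- ifelse(chans %in% c("Oz", "O1", "O2"),
                 params$occipital_gain, params$other_gain)

  cube <- array(0, dim = c(n_tr, n_chan, n_samp),
                dimnames = list(NULL, chans, NULL))
  noise <- onef_noise(n_tr * n_chan, n_samp, params$noise_exponent,
                      params$noise_amp, fs)
  dim(noise) <- c(n_samp, n_chan, n_tr)
  for (ch in seq_len(n_chan))
    cube[, ch, ] <- gain[ch] * wave + t(noise[, ch, ])

  tt <- data.frame(subject = subject_id, group = group,
                   trial_id = seq_len(n_tr), condition = cond, rt = rt,
                   correct = correct, artifact = FALSE,
                   true_alpha_amp = amp, true_alpha_power = amp^2,
                   stringsAsFactors = FALSE)
  rec <- new_recording(cube, fs, times, chans, tt)
  rec$alpha_freq <- f_alpha       # ground truth, for recovery checks
  rec
}

new_recording <- function(data, fs, times, channel_names, trial_table) {
  stopifnot(dim(data)[1] == nrow(trial_table),
            dim(data)[2] == length(channel_names),
            dim(data)[3] == length(times))
  structure(list(data = data, fs = fs, times = times,
                 channel_names = channel_names, trial_table = trial_table),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoched_recording: %d trials x %d channels x %d samples, fs = %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g..%g ms; channels: %s\n", min(x$times), max(x$times),
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

# latent Gaussian pairs carrying the target Spearman rho; trials whose RT
# falls below rt_min are redrawn as pairs (truncation by resampling)
copula_pairs <- function(n, rho, rt_mean, rt_sd, rt_min) {
  r <- 2 * sin(pi * rho / 6)
  u <- numeric(n); v <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    uu <- stats::rnorm(m)
    vv <- r * uu + sqrt(1 - r^2) * stats::rnorm(m)
    u[need] <- uu; v[need] <- vv
    need <- need[rt_mean + rt_sd * vv < rt_min]
  }
  list(u = u, rt = rt_mean + rt_sd * v)
}

# columns of 1/f^beta noise, each scaled to `amp` RMS. Spectral shaping of
# white Gaussian noise: scale DFT coefficients by f^(-beta/2), zero DC.
# The white spectrum is drawn complex (no Hermitian symmetry): after the
# symmetric shaping, the real and imaginary parts of the inverse DFT are
# two independent shaped-noise columns, halving the FFT work.
onef_noise <- function(n_cols, n_samp, beta, amp, fs) {
  if (amp <= 0) return(matrix(0, n_samp, n_cols))
  nfft <- smooth_length(n_samp)
  f <- seq(0, fs - fs / nfft, length.out = nfft)
  f[f > fs / 2] <- fs - f[f > fs / 2]          # fold to physical frequency
  shape <- c(0, f[-1]^(-beta / 2))
  n2 <- ceiling(n_cols / 2)
  w <- matrix(complex(real = stats::rnorm(nfft * n2),
                      imaginary = stats::rnorm(nfft * n2)), nfft, n2)
  y <- stats::mvfft(w * shape, inverse = TRUE)
  x <- matrix(0, n_samp, 2 * n2)
  x[, seq(1, 2 * n2, by = 2)] <- Re(y[seq_len(n_samp), , drop = FALSE])
  x[, seq(2, 2 * n2, by = 2)] <- Im(y[seq_len(n_samp), , drop = FALSE])
  x <- x[, seq_len(n_cols), drop = FALSE]
  rms <- sqrt(colMeans(x^2))
  sweep(x, 2, amp / rms, `*`)
}

# next FFT-friendly length (2^a * 3^b * 5^c)
smooth_length <- function(n) {
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
    k <- k + 1
  }
}

#' Simulate a two-group cohort with neuropsychological scores
#'
#' Draws `n_per_group` HC and `n_per_group` MCI subjects via
#' [simulate_subject()], with per-subject seeds fanned out deterministically
#' from `params$seed`, plus a cohort table of neuropsychological test scores
#' drawn normal with group-specific means and SDs (defaults in
#' [neuropsych_defaults()]).
#'
#' @param params a [sim_params()] object.
#' @param npsych_means optional list overriding [neuropsych_defaults()].
#' @return list with `recordings` (list of `epoched_recording`) and
#'   `neuropsych` (one row per subject: subject, group, 11 test scores).
#' @export
simulate_cohort <- function(params, npsych_means = neuropsych_defaults()) {
  stopifnot(inherits(params, "sim_params"), params$n_per_group >= 2)
  groups <- rep(c("HC", "MCI"), each = params$n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "HC", "hc", "mci"),
                 c(seq_len(params$n_per_group), seq_len(params$n_per_group)))
  recs <- vector("list", length(ids))
  for (i in seq_along(ids))
    recs[[i]] <- simulate_subject(params, groups[i],
                                  subject_seed = child_seed(params$seed, i),
                                  subject_id = ids[i])
  names(recs) <- ids

  set.seed(child_seed(params$seed, 0))
  tests <- rownames(npsych_means$mean)
  np <- data.frame(subject = ids, group = groups, stringsAsFactors = FALSE)
  for (tn in tests)
    np[[tn]] <- stats::rnorm(length(ids),
                             npsych_means$mean[tn, groups],
                             npsych_means$sd[tn, groups])
  list(recordings = recs, neuropsych = np)
}

#' Default neuropsychological score distributions and norms
#'
#' Group means and SDs for the MMSE and the ten neuropsychological tests
#' covering five cognitive domains (memory: AVLT delayed/total, ROCFT
#' recall; executive: TMT-B, Stroop; attention: TMT-A, SDMT; language: CVFT,
#' BNT; visuospatial: ROCFT copy, CDT). TMT-A/B and Stroop are completion
#' times, so higher scores are worse. The `norms` component (used by the
#' 1.5-SD labeling rule) is a synthetic stand-in set to the HC
#' distribution, since published normative tables are external data.
#'
#' @return list with matrices `mean` and `sd` (tests x groups HC/MCI),
#'   `norms` (data.frame test, mean, sd), `higher_worse` (character), and
#'   `domains` (named list mapping cognitive domain to tests).
#' @export
neuropsych_defaults <- function() {
  tests <- c("MMSE", "AVLT_delayed", "AVLT_total", "ROCFT_recall",
             "TMT_B", "Stroop", "TMT_A", "SDMT", "CVFT", "BNT",
             "ROCFT_copy", "CDT")
  mci_m <- c(26.64, 3.36, 19.36, 8.46, 230.46, 95.89, 71.75, 25.75,
             15.00, 20.11, 29.82, 21.46)
  mci_s <- c(1.50, 2.72, 9.80, 6.70, 72.10, 33.46, 22.04, 11.80,
             4.82, 3.70, 6.35, 6.27)
  hc_m <- c(28.39, 6.14, 29.50, 15.75, 153.25, 83.64, 53.36, 34.92,
            18.79, 24.75, 33.71, 25.75)
  hc_s <- c(1.20, 1.96, 6.70, 5.83, 58.21, 24.03, 14.55, 10.31,
            5.49, 3.11, 3.43, 4.46)
  m <- cbind(HC = hc_m, MCI = mci_m); rownames(m) <- tests
  s <- cbind(HC = hc_s, MCI = mci_s); rownames(s) <- tests
  list(mean = m, sd = s,
       norms = data.frame(test = tests, mean = hc_m, sd = hc_s,
                          stringsAsFactors = FALSE),
       higher_worse = c("TMT_A", "TMT_B", "Stroop"),
       domains = list(memory = c("AVLT_delayed", "AVLT_total", "ROCFT_recall"),
                      executive = c("TMT_B", "Stroop"),
                      attention = c("TMT_A", "SDMT"),
                      language = c("CVFT", "BNT"),
                      visuospatial = c("ROCFT_copy", "CDT")))
}

#' Label a subject MCI or HC from neuropsychological scores
#'
#' Applies the 1.5-SD domain-dysfunction rule: a subject is labeled MCI if
#' any test in any cognitive domain deviates more than 1.5 norm SDs from the
#' norm mean in the impaired direction (strictly below mean - 1.5 SD, or
#' strictly above mean + 1.5 SD for timed tests where higher is worse). A
#' score exactly at the cutoff does not count as dysfunction.
#'
#' @param scores named list/one-row data.frame with a value for every test
#'   mapped by `domains`.
#' @param norms data.frame with columns test, mean, sd.
#' @param domains named list mapping domains to test names.
#' @param higher_worse tests where larger scores indicate impairment.
#' @return `"MCI"` or `"HC"`.
#' @export
classify_mci <- function(scores, norms = neuropsych_defaults()$norms,
                         domains = neuropsych_defaults()$domains,
                         higher_worse = neuropsych_defaults()$higher_worse) {
  for (tests in domains) for (tn in tests) {
    v <- scores[[tn]]
    if (is.null(v) || is.na(v)) stop("missing score for test ", tn)
    i <- match(tn, norms$test)
    if (is.na(i)) stop("no norm for test ", tn)
    cut <- 1.5 * norms$sd[i]
    dev <- if (tn %in% higher_worse) v - norms$mean[i] else norms$mean[i] - v
    if (dev > cut) return("MCI")
  }
  "HC"
}

#' Simulate per-trial alpha power and RT without waveforms
#'
#' The statistical core of the generator: per-trial (true alpha power, RT)
#' pairs from the same Gaussian copula as [simulate_subject()], optionally
#' with multiplicative lognormal measurement noise on power. Used for
#' calibration studies (e.g. ANOVA type-I error under the null) where
#' synthesizing and transforming waveforms would add nothing but runtime.
#'
#' @param n_trials trials per condition.
#' @param rho target Spearman correlation (scalar or per-condition pair).
#' @param rt_mean,rt_sd,rt_min RT distribution per condition, ms.
#' @param amp_meanlog,amp_sdlog lognormal amplitude parameters.
#' @param power_noise_sdlog sdlog of multiplicative noise on measured power
#'   (0 = noiseless).
#' @return data.frame: condition, rt, alpha_power, true_alpha_power.
#' @export
simulate_coupling_table <- function(n_trials = 60, rho = 0.1,
                                    rt_mean = c(498, 538),
                                    rt_sd = c(55, 58), rt_min = 150,
                                    amp_meanlog = 0, amp_sdlog = 0.4,
                                    power_noise_sdlog = 0) {
  if (length(rho) == 1) rho <- c(rho, rho)
  conds <- c("congruent", "incongruent")
  out <- vector("list", 2)
  for (k in 1:2) {
    uv <- copula_pairs(n_trials, rho[k], rt_mean[k], rt_sd[k], rt_min)
    a2 <- stats::qlnorm(stats::pnorm(uv$u), amp_meanlog, amp_sdlog)^2
    meas <- if (power_noise_sdlog > 0)
      a2 * stats::rlnorm(n_trials, 0, power_noise_sdlog) else a2
    out[[k]] <- data.frame(condition = conds[k], rt = uv$rt,
                           alpha_power = meas, true_alpha_power = a2,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
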