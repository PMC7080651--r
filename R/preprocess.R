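#' Re-reference epochs to the average of all electrodes
#'
#' Subtracts, at every trial and time point, the mean across channels, so
#' the across-channel mean of the output is zero everywhere (common average
#' reference).
#'
#' @param rec an `epoched_recording`.
#' @return the re-referenced `epoched_recording`.
#' @export
rereference_average <- function(rec) {
  d <- rec$data
  n_ch <- dim(d)[2]
  if (n_ch < 2) stop("average reference needs at least 2 channels")
  m <- colMeans(aperm(d, c(2, 1, 3)))       # trials x samples
  rec$data <- d - aperm(array(m, dim = dim(d)[c(1, 3, 2)]), c(1, 3, 2))
  rec
}

#' Zero-phase FIR band-pass filter
#'
#' Filters every trial and channel with a linear-phase windowed-sinc
#' (Hamming) band-pass kernel, applied by FFT convolution with exact
#' compensation of the integer group delay, so the net filter is zero-phase.
#' The kernel is the difference of two Hamming-windowed-sinc low-pass
#' kernels, which allows different transition bandwidths at the two edges:
#' `min(max(0.25 * lo, 2), lo)` Hz at the low edge and `0.25 * hi` Hz at the
#' high edge (each edge sits at its -6 dB point, the usual windowed-sinc
#' convention). Epoch ends are treated as zero-padded; the outermost
#' half-kernel-width of each epoch is therefore attenuated, which is
#' irrelevant to the prestimulus region of interest.
#'
#' @param rec an `epoched_recording`.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @return the filtered `epoched_recording`.
#' @export
bandpass_fir <- function(rec, lo = 1, hi = 30) {
  fs <- rec$fs
  if (!(lo > 0 && lo < hi && hi < fs / 2)) stop("need 0 < lo < hi < fs/2")
  h <- fir_bandpass_kernel(lo, hi, fs)
  d <- rec$data
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_s <- dim(d)[3]
  # columns = trial x channel signals
  x <- matrix(aperm(d, c(3, 1, 2)), nrow = n_s)
  y <- fft_filter_zerophase(x, h)
  rec$data <- aperm(array(y, dim = c(n_s, n_tr, n_ch)), c(2, 3, 1))
  dimnames(rec$data) <- dimnames(d)
  rec
}

# symmetric band-pass kernel as difference of two centered low-pass kernels
fir_bandpass_kernel <- function(lo, hi, fs) {
  tb_lo <- min(max(0.25 * lo, 2), lo)
  tb_hi <- 0.25 * hi
  h_hi <- windowed_sinc_lowpass(hi, tb_hi, fs)
  h_lo <- windowed_sinc_lowpass(lo, tb_lo, fs)
  n <- max(length(h_hi), length(h_lo))     # both odd; center-align
  pad <- function(h) {
    k <- (n - length(h)) / 2
    c(rep(0, k), h, rep(0, k))
  }
  pad(h_hi) - pad(h_lo)
}

# odd-length Hamming-windowed sinc low-pass with -6 dB point at `fc`
windowed_sinc_lowpass <- function(fc, tb, fs) {
  m <- ceiling(3.3 * fs / tb)              # Hamming main-lobe factor
  if (m %% 2 == 1) m <- m + 1
  n <- m + 1
  k <- seq(-m / 2, m / 2)
  x <- 2 * fc / fs * k
  h <- 2 * fc / fs * ifelse(k == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.54 + 0.46 * cos(2 * pi * k / m)
  h <- h * w
  h / sum(h)                               # unit DC gain
}

# zero-phase filtering of the columns of x with an odd symmetric kernel h.
# The kernel is wrapped so its center sits at index 1, making its DFT real
# (a zero-phase transfer function); two real columns are packed into one
# complex FFT (Re/Im stay separated because the transfer function is real).
fft_filter_zerophase <- function(x, h) {
  n_s <- nrow(x); n_h <- length(h); half <- (n_h - 1) / 2
  nfft <- smooth_length(n_s + half)
  hw <- numeric(nfft)
  hw[1:(half + 1)] <- h[(half + 1):n_h]
  hw[(nfft - half + 1):nfft] <- h[1:half]
  H <- Re(stats::fft(hw))
  n_c <- ncol(x)
  xp <- rbind(x, matrix(0, nfft - n_s, n_c))
  odd <- seq(1, n_c, by = 2)
  even <- odd + 1
  z <- xp[, odd, drop = FALSE] + (0+1i) *
    (if (n_c %% 2 == 0) xp[, even, drop = FALSE]
     else cbind(xp[, even[-length(even)], drop = FALSE], 0))
  Y <- stats::mvfft(stats::mvfft(z) * H, inverse = TRUE) / nfft
  y <- matrix(0, n_s, n_c)
  y[, odd] <- Re(Y[seq_len(n_s), , drop = FALSE])
  y[, even[even <= n_c]] <- Im(Y[seq_len(n_s),
                                 seq_along(even[even <= n_c]),
                                 drop = FALSE])
  y
}

#' Baseline-correct epochs
#'
#' Subtracts from every trial x channel trace its time-domain mean over the
#' baseline window (default the whole prestimulus interval, -2000..0 ms).
#'
#' @param rec an `epoched_recording`.
#' @param window ms pair inside the epoch.
#' @return the corrected `epoched_recording`.
#' @export
baseline_correct <- function(rec, window = c(-2000, 0)) {
  idx <- which(rec$times >= window[1] & rec$times <= window[2])
  if (!length(idx) || window[1] < min(rec$times) || window[2] > max(rec$times))
    stop("baseline window outside epoch")
  m <- rowMeans(rec$data[, , idx, drop = FALSE], dims = 2)
  rec$data <- rec$data - as.vector(m)      # recycles over samples
  rec
}

#' Flag invalid, incorrect and outlier trials and recompute inclusion
#'
#' A trial is invalid when no response was recorded within the response
#' window (`rt_max` ms after stimulus onset: 250 ms stimulus + 2000 ms
#' post-stimulus fixation by default). Among valid-response trials, the
#' per-condition mean and SD of RT are computed in a single pass and trials
#' outside the closed interval mean +/- 2 SD are flagged as outliers (with
#' SD = 0 the interval degenerates to the mean and equality still counts as
#' inside). `included` — the trials entering EEG analyses — requires a valid
#' response, a correct response, no artifact mask, and no outlier flag.
#' The operation is idempotent: flags are recomputed from scratch.
#'
#' @param table a trial table with columns condition, rt, correct, artifact.
#' @param rt_max response window end, ms from stimulus onset.
#' @param min_trials minimum included trials per condition below which the
#'   subject is signalled unusable.
#' @return the table with valid, outlier, included columns (re)computed.
#' @export
exclude_trials <- function(table, rt_max = 2250, min_trials = 4) {
  stopifnot(all(c("condition", "rt", "correct") %in% names(table)))
  if (is.null(table$artifact)) table$artifact <- FALSE
  table$valid <- !is.na(table$rt) & table$rt <= rt_max
  table$outlier <- FALSE
  for (cn in unique(table$condition)) {
    i <- which(table$condition == cn & table$valid)
    m <- mean(table$rt[i]); s <- stats::sd(table$rt[i])
    if (is.na(s)) s <- 0
    table$outlier[i] <- table$rt[i] < m - 2 * s | table$rt[i] > m + 2 * s
  }
  table$included <- table$valid & table$correct & !table$artifact &
    !table$outlier
  n_inc <- tapply(table$included, table$condition, sum)
  if (any(n_inc < min_trials))
    stop("unusable subject: fewer than ", min_trials,
         " included trials in condition ",
         paste(names(n_inc)[n_inc < min_trials], collapse = ", "))
  if (is.null(table$speed_bin)) table$speed_bin <- "unassigned"
  table
}

#' Per-condition behavioral summary
#'
#' Mean and SD of RT per condition over included trials; error rate per
#' condition as the proportion of incorrect responses among valid-response
#' trials; flanker effects as incongruent minus congruent differences.
#'
#' @param table a trial table after [exclude_trials()].
#' @return one-row data.frame: mean_rt/sd_rt/er per condition, flanker_rt,
#'   flanker_er.
#' @export
behavioral_summary <- function(table) {
  stopifnot(!is.null(table$included))
  res <- list()
  for (cn in c("congruent", "incongruent")) {
    inc <- table$condition == cn & table$included
    if (!any(inc)) stop("no included trials in condition ", cn)
    resp <- table$condition == cn & table$valid
    key <- if (cn == "congruent") "cong" else "incong"
    res[[paste0("mean_rt_", key)]] <- mean(table$rt[inc])
    res[[paste0("sd_rt_", key)]] <- stats::sd(table$rt[inc])
    res[[paste0("er_", key)]] <- mean(!table$correct[resp])
  }
  res$flanker_rt <- res$mean_rt_incong - res$mean_rt_cong
  res$flanker_er <- res$er_incong - res$er_cong
  as.data.frame(res)
}
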