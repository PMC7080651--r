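#' Single-trial spectrogram via a windowed Fourier transform
#'
#' For every output time t (on a regular grid, default -2000..+1000 ms in
#' 2 ms steps) the signal segment centered on t (window of `window_len` ms;
#' at 500 Hz and 300 ms, 150 samples — the "center" of the even-length
#' window is sample 75, 0-based, i.e. 75 samples before and 74 after) is
#' multiplied by a symmetric Hanning taper, zero-padded at its end to
#' `pad_to` samples, and discrete-Fourier transformed; the spectrogram is
#' P(t, f) = |F(t, f)|^2 at the retained frequency bins (1 Hz spacing when
#' `pad_to = fs`, bins 1..`f_max` Hz). Segments reaching past the epoch
#' edges are zero-padded symmetrically. No taper amplitude-gain
#' compensation is applied, so absolute power is convention-dependent; all
#' downstream statistics are within-subject and scale-invariant.
#'
#' Two numerically identical engines are provided: `"segment"` transforms
#' each padded segment directly (the definition above, used as reference),
#' while `"filterbank"` evaluates the same sums as one FFT convolution per
#' frequency bin, which is much faster when only a frequency subset is
#' needed. `"auto"` picks the filterbank.
#'
#' @param rec an `epoched_recording`.
#' @param window_len taper length, ms.
#' @param pad_to padded segment length, samples; frequency bin spacing is
#'   `fs / pad_to` Hz.
#' @param t_step output time step, ms (must be a multiple of the sample
#'   period).
#' @param f_max highest retained frequency, Hz.
#' @param freqs frequency bins to retain, Hz (default `1:f_max` at the
#'   native bin spacing).
#' @param channels channel subset (default all).
#' @param t_range ms pair restricting output times (default whole epoch).
#' @param engine `"auto"`, `"segment"` or `"filterbank"`.
#' @return a `tf_map`: list with `power` (trials x channels x freqs x
#'   times, microvolt^2), `freqs`, `times`, `channel_names`, `window_len`,
#'   `pad_to`.
#' @export
wft_spectrogram <- function(rec, window_len = 300, pad_to = 500, t_step = 2,
                            f_max = 30, freqs = NULL, channels = NULL,
                            t_range = NULL,
                            engine = c("auto", "segment", "filterbank")) {
  engine <- match.arg(engine)
  fs <- rec$fs
  n_win <- round(window_len / 1000 * fs)
  if (pad_to < n_win) stop("pad_to must be at least the window length")
  samp_ms <- 1000 / fs
  if (abs(t_step / samp_ms - round(t_step / samp_ms)) > 1e-9)
    stop("t_step must be a multiple of the sample period")
  step <- as.integer(round(t_step / samp_ms))

  df <- fs / pad_to
  if (is.null(freqs)) freqs <- seq(df, f_max, by = df)
  bins <- freqs / df
  if (any(abs(bins - round(bins)) > 1e-9))
    stop("requested freqs must sit on the fs/pad_to grid")
  bins <- as.integer(round(bins))

  if (is.null(channels)) channels <- rec$channel_names
  ch_idx <- match(channels, rec$channel_names)
  if (anyNA(ch_idx)) stop("unknown channel(s): ",
                          paste(channels[is.na(ch_idx)], collapse = ", "))

  t_idx <- seq(1L, length(rec$times), by = step)
  if (!is.null(t_range))
    t_idx <- t_idx[rec$times[t_idx] >= t_range[1] &
                     rec$times[t_idx] <= t_range[2]]
  out_times <- rec$times[t_idx]

  taper <- hanning_taper(n_win)
  half <- n_win %/% 2                       # center = 0-based index n_win/2
  n_tr <- dim(rec$data)[1]
  pow <- array(0, dim = c(n_tr, length(ch_idx), length(bins), length(t_idx)))

  if (engine == "segment") {
    pad0 <- rep(0, pad_to - n_win)
    for (ch in seq_along(ch_idx)) for (tr in seq_len(n_tr)) {
      x <- rec$data[tr, ch_idx[ch], ]
      seg <- matrix(0, pad_to, length(t_idx))
      for (j in seq_along(t_idx)) {
        lo <- t_idx[j] - half
        src <- max(1L, lo):min(length(x), lo + n_win - 1L)
        seg[src - lo + 1L, j] <- x[src] * taper[src - lo + 1L]
      }
      Fm <- stats::mvfft(seg)[bins + 1L, , drop = FALSE]
      pow[tr, ch, , ] <- Mod(Fm)^2
    }
  } else {
    # F(c, k) = sum_n x[c - half + n] g_k[n], g_k[n] = w[n] e^{-2 pi i k n / pad_to}
    # = a sliding inner product, computed for all c at once as an FFT
    # convolution of x with the reversed kernel rev(g_k).
    n_s <- dim(rec$data)[3]
    nfft <- smooth_length(n_s + n_win - 1L)
    n <- seq_len(n_win) - 1
    G <- vapply(bins, function(k) {
      g <- taper * exp(-2i * pi * k * n / pad_to)
      stats::fft(c(rev(g), rep(0, nfft - n_win)))
    }, complex(nfft))
    x <- matrix(aperm(rec$data[, ch_idx, , drop = FALSE], c(3, 1, 2)),
                nrow = n_s)                 # samples x (trial*channel)
    X <- stats::mvfft(rbind(x, matrix(0, nfft - n_s, ncol(x))))
    # conv index: y[m] = sum_j x[j] grev[m - j + 1]; F(c,k) = y[c - half + n_win - 1]
    pick <- t_idx - half + n_win - 1L
    for (kk in seq_along(bins)) {
      y <- stats::mvfft(X * G[, kk], inverse = TRUE) / nfft
      p <- Mod(y[pick, , drop = FALSE])^2   # times x (trial*channel)
      pow[, , kk, ] <- aperm(array(p, c(length(t_idx), n_tr,
                                        length(ch_idx))), c(2, 3, 1))
    }
  }
  structure(list(power = pow, freqs = freqs, times = out_times,
                 channel_names = channels, window_len = window_len,
                 pad_to = pad_to, fs = fs),
            class = "tf_map")
}

# symmetric Hanning taper, endpoints zero (MATLAB hann(n, "symmetric"))
hanning_taper <- function(n) {
  k <- seq_len(n) - 1
  0.5 * (1 - cos(2 * pi * k / (n - 1)))
}

#' Alpha region-of-interest definition
#'
#' The prestimulus alpha ROI: -1000..-300 ms, 7..14 Hz (both inclusive),
#' occipital electrodes Oz, O1, O2.
#' @param t_min,t_max ms bounds. @param f_min,f_max Hz bounds.
#' @param electrodes channel names averaged over.
#' @return list with the five fields.
#' @export
alpha_roi <- function(t_min = -1000, t_max = -300, f_min = 7, f_max = 14,
                      electrodes = c("Oz", "O1", "O2")) {
  list(t_min = t_min, t_max = t_max, f_min = f_min, f_max = f_max,
       electrodes = electrodes)
}

#' Extract per-trial prestimulus alpha power
#'
#' Per trial, the mean of P(t, f) over every grid point with t and f inside
#' the (inclusive) ROI bounds, computed per channel and then averaged over
#' the ROI electrodes (counts are equal, so this equals pooling).
#'
#' @param tf a `tf_map`.
#' @param roi an [alpha_roi()] list.
#' @return numeric vector, one mean power (microvolt^2) per trial.
#' @export
extract_alpha_power <- function(tf, roi = alpha_roi()) {
  ch <- match(roi$electrodes, tf$channel_names)
  if (anyNA(ch)) stop("ROI electrode(s) missing from TF map: ",
                      paste(roi$electrodes[is.na(ch)], collapse = ", "))
  ti <- which(tf$times >= roi$t_min & tf$times <= roi$t_max)
  fi <- which(tf$freqs >= roi$f_min & tf$freqs <= roi$f_max)
  if (!length(ti) || !length(fi)) stop("ROI outside TF map grid")
  sub <- tf$power[, ch, fi, ti, drop = FALSE]
  per_chan <- apply(sub, c(1, 2), mean)     # trials x channels
  rowMeans(per_chan)
}
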