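make_rec <- function(cube, fs = 500, window = c(-2000, 1000)) {
  times <- seq(window[1], window[2], by = 1000 / fs)
  stopifnot(dim(cube)[3] == length(times))
  chans <- dimnames(cube)[[2]] %||% paste0("ch", seq_len(dim(cube)[2]))
  tt <- data.frame(subject = "t", group = "HC",
                   trial_id = seq_len(dim(cube)[1]),
                   condition = "congruent", rt = 500, correct = TRUE,
                   artifact = FALSE)
  prealpha:::new_recording(cube, fs, times, chans, tt)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("average reference removes the common mode and zeroes the channel mean", {
  set.seed(1)
  cube <- array(rnorm(2 * 3 * 1501), dim = c(2, 3, 1501))
  rec <- rereference_average(make_rec(cube))
  means <- apply(rec$data, c(1, 3), mean)
  expect_lt(max(abs(means)), 1e-12)
  # two channels with values (x, -x) are already average-referenced
  x <- array(0, dim = c(1, 2, 1501))
  x[1, 1, ] <- sin(1:1501); x[1, 2, ] <- -sin(1:1501)
  expect_equal(rereference_average(make_rec(x))$data, x)
  # a common offset on all channels is rejected entirely
  off <- cube + 7
  expect_equal(rereference_average(make_rec(off))$data,
               rereference_average(make_rec(cube))$data)
  expect_error(rereference_average(make_rec(cube[, 1, , drop = FALSE])),
               "2 channels")
})

test_that("band-pass response: passband flat, stopband and DC attenuated", {
  fs <- 500
  gain_at <- function(freq) {
    times <- seq(-2000, 1000, by = 2)
    cube <- array(sin(2 * pi * freq * times / 1000), dim = c(1, 2, 1501))
    out <- bandpass_fir(make_rec(cube), 1, 30)
    # measure away from the (zero-padded) epoch edges
    mid <- 400:1100
    sqrt(mean(out$data[1, 1, mid]^2) / mean(cube[1, 1, mid]^2))
  }
  expect_lt(abs(gain_at(10) - 1), 0.05)
  expect_lt(gain_at(45), 0.1)            # >= 20 dB down
  # DC: constant input must be suppressed by >= 20 dB
  cube <- array(1, dim = c(1, 2, 1501))
  out <- bandpass_fir(make_rec(cube), 1, 30)
  expect_lt(sqrt(mean(out$data[1, 1, 400:1100]^2)), 0.1)
  expect_error(bandpass_fir(make_rec(cube), 30, 1), "lo < hi")
})

test_that("band-pass agrees with an independent zero-phase FIR reference", {
  skip_if_not_installed("signal")
  set.seed(4)
  fs <- 500
  x <- rnorm(1501)
  cube <- array(rep(x, each = 2), dim = c(1, 2, 1501))
  mine <- bandpass_fir(make_rec(cube), 1, 30)$data[1, 1, ]
  # independent design (signal::fir1) applied as a centered single-pass
  # convolution: symmetric kernel -> zero phase
  b <- signal::fir1(500, c(1, 30) / (fs / 2), "pass")
  ref <- stats::filter(x, b, sides = 2)
  mid <- 400:1100
  expect_gt(cor(mine[mid], as.numeric(ref[mid])), 0.98)
  expect_lt(abs(sd(mine[mid]) / sd(ref[mid]) - 1), 0.1)
})

test_that("baseline correction subtracts the window mean exactly", {
  cube <- array(3.5, dim = c(2, 2, 1501))
  out <- baseline_correct(make_rec(cube))
  expect_equal(max(abs(out$data)), 0)
  # zero-mean sinusoid over the window is untouched
  times <- seq(-2000, 1000, by = 2)
  base <- times >= -2000 & times <= 0
  s <- sin(2 * pi * 10 * times / 1000)
  s <- s - mean(s[base])
  cube2 <- array(rep(s, each = 4), dim = c(2, 2, 1501))
  out2 <- baseline_correct(make_rec(cube2))
  expect_equal(out2$data, cube2, tolerance = 1e-12)
  # shift invariance
  out3 <- baseline_correct(make_rec(cube2 + 7))
  expect_equal(out3$data, out2$data, tolerance = 1e-12)
  expect_error(baseline_correct(make_rec(cube2), window = c(-3000, 0)),
               "outside epoch")
})

test_that("re-reference and band-pass commute to numerical tolerance", {
  set.seed(9)
  cube <- array(rnorm(2 * 3 * 1501), dim = c(2, 3, 1501))
  a <- bandpass_fir(rereference_average(make_rec(cube)), 1, 30)$data
  b <- rereference_average(bandpass_fir(make_rec(cube), 1, 30))$data
  expect_equal(a, b, tolerance = 1e-10)
})

trial_tab <- function(rt, condition = "congruent", correct = TRUE,
                      artifact = FALSE) {
  data.frame(subject = "t", group = "HC", trial_id = seq_along(rt),
             condition = condition, rt = rt, correct = correct,
             artifact = artifact)
}

test_that("RT outliers are flagged per condition with a closed 2-SD interval", {
  # {500 x 19, 2000}: mean 575, sd 336.6 -> 2000 outside [  -98, 1248]
  tab <- exclude_trials(trial_tab(c(rep(500, 19), 2000)))
  expect_equal(which(tab$outlier), 20)
  expect_equal(sum(tab$included), 19)
  # all identical RTs: SD 0, bounds degenerate to the mean, none excluded
  tab2 <- exclude_trials(trial_tab(rep(480, 10)))
  expect_false(any(tab2$outlier))
  # incorrect trial: out of EEG analyses but still counted in the ER
  tab3 <- exclude_trials(trial_tab(
    rep(c(400, 500), 15),
    condition = rep(c("congruent", "incongruent"), c(20, 10)),
    correct = c(FALSE, rep(TRUE, 29))))
  expect_false(tab3$included[1])
  expect_true(tab3$valid[1])
  s <- behavioral_summary(tab3)
  expect_equal(s$er_cong, 0.05)
})

test_that("outlier bounds are computed per condition, never pooled", {
  cond <- rep(c("congruent", "incongruent"), each = 10)
  cong <- c(rep(500, 9), 700)        # 700 is 4 within-condition SDs out
  a <- exclude_trials(trial_tab(c(cong, rep(540, 10)), condition = cond))
  b <- exclude_trials(trial_tab(c(cong, rep(2200, 10)), condition = cond))
  expect_equal(which(a$outlier), 10)
  # radically different incongruent RTs leave congruent flags untouched
  expect_identical(a$outlier[1:10], b$outlier[1:10])
  expect_identical(a$included[1:10], b$included[1:10])
})

test_that("exclusion is idempotent and respects the response window", {
  rt <- c(rep(500, 18), 2400, NA)
  tab <- trial_tab(rt)
  once <- exclude_trials(tab)
  twice <- exclude_trials(once)
  expect_identical(once, twice)
  expect_false(once$valid[19])   # beyond the 2250 ms response window
  expect_false(once$valid[20])   # no response
  expect_error(exclude_trials(trial_tab(c(500, 510, 520, NA))),
               "unusable subject")
})

test_that("behavioral summary computes condition means and flanker effects", {
  rt <- c(rep(500, 10), rep(540, 10))
  cond <- rep(c("congruent", "incongruent"), each = 10)
  tab <- exclude_trials(trial_tab(rt, condition = cond))
  s <- behavioral_summary(tab)
  expect_equal(s$flanker_rt, 40)
  expect_equal(s$flanker_er, 0)
  expect_equal(s$mean_rt_cong, 500)
  expect_equal(s$sd_rt_incong, 0)
})
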