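# Independent reference implementations used to check the package's
# computational paths. These stay deliberately naive.

# O(N^2) discrete Fourier transform by direct summation
naive_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * k / n)), complex(1))
}

# exhaustive pair-counting AUC (ties count one half)
pair_count_auc <- function(scores, labels, positive = TRUE) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Balanced mixed-design ANOVA by full enumeration over marginal means.
# data: long data.frame with subject, one between factor, within factors
# and a value column. Effects via inclusion-exclusion over marginal means;
# error strata via the subject(-within-group) x within-effect terms.
enumeration_anova <- function(data, dv, between, within, subject) {
  data <- as.data.frame(data)
  margin_mean <- function(fac) {
    if (!length(fac)) return(rep(mean(data[[dv]]), nrow(data)))
    key <- interaction(data[fac], drop = TRUE)
    ave(data[[dv]], key)
  }
  subsets_of <- function(v) {
    out <- list(character(0))
    for (k in seq_along(v))
      out <- c(out, combn(v, k, simplify = FALSE))
    out
  }
  effect_col <- function(S) {
    val <- rep(0, nrow(data))
    for (T in subsets_of(S))
      val <- val + (-1)^(length(S) - length(T)) * margin_mean(T)
    val
  }
  n_subj <- length(unique(data[[subject]]))
  n_grp <- length(unique(data[[between]]))
  lev <- vapply(c(within, setNames(between, between)),
                function(f) length(unique(data[[f]])), 1)
  names(lev) <- c(within, between)

  # error strata
  subj_mean <- margin_mean(subject)
  grp_mean <- margin_mean(between)
  ss_err_between <- sum((subj_mean - grp_mean)^2)
  df_err_between <- n_subj - n_grp
  err_within <- function(E) {
    val <- rep(0, nrow(data))
    for (T in subsets_of(E)) {
      sgn <- (-1)^(length(E) - length(T))
      val <- val + sgn * (margin_mean(c(subject, T)) -
                            margin_mean(c(between, T)))
    }
    list(ss = sum(val^2),
         df = (n_subj - n_grp) * prod(lev[E] - 1))
  }

  effects <- subsets_of(c(between, within))
  effects <- effects[lengths(effects) > 0]
  rows <- lapply(effects, function(S) {
    ssS <- sum(effect_col(S)^2)
    dfS <- prod(lev[S] - 1)
    E <- S[S %in% within]
    if (length(E)) {
      er <- err_within(E)
      ss_err <- er$ss; df_err <- er$df
    } else {
      ss_err <- ss_err_between; df_err <- df_err_between
    }
    data.frame(effect = paste(S, collapse = ":"),
               df_num = dfS, df_den = df_err,
               F = (ssS / dfS) / (ss_err / df_err),
               ss = ssS, ss_err = ss_err, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# a random balanced mixed-design dataset
random_mixed_data <- function(n_per_group, within_levels, seed) {
  set.seed(seed)
  within <- lapply(within_levels, function(k) paste0("l", seq_len(k)))
  cells <- expand.grid(within, stringsAsFactors = FALSE)
  names(cells) <- names(within_levels)
  subj <- paste0("s", seq_len(2 * n_per_group))
  grp <- rep(c("A", "B"), each = n_per_group)
  out <- do.call(rbind, lapply(seq_along(subj), function(i)
    cbind(subject = subj[i], group = grp[i], cells,
          stringsAsFactors = FALSE)))
  out$value <- rnorm(nrow(out))
  out
}

# small noiseless recording with a single pure tone on every channel
tone_recording <- function(freq, amp = 1, fs = 500, n_trials = 2,
                           channels = c("Oz", "O1", "O2", "Cz"),
                           window = c(-2000, 1000)) {
  times <- seq(window[1], window[2], by = 1000 / fs)
  cube <- array(0, dim = c(n_trials, length(channels), length(times)),
                dimnames = list(NULL, channels, NULL))
  for (tr in seq_len(n_trials)) for (ch in seq_along(channels))
    cube[tr, ch, ] <- amp * sin(2 * pi * freq * times / 1000)
  tt <- data.frame(subject = "t", group = "HC",
                   trial_id = seq_len(n_trials),
                   condition = rep(c("congruent", "incongruent"),
                                   length.out = n_trials),
                   rt = 500 + seq_len(n_trials), correct = TRUE,
                   artifact = FALSE, stringsAsFactors = FALSE)
  prealpha:::new_recording(cube, fs, times, channels, tt)
}
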