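#' Median-split trials into fast and slow bins
#'
#' Within each condition's included trials, computes the median RT and
#' assigns trials with RT strictly below the median to the fast bin and all
#' others (strictly above, or exactly at, the median) to the slow bin: fast
#' is defined strictly ("less than the median"), so median-tied trials fall
#' in the slow bin. The split is per condition by default because the
#' speed x congruency ANOVA crosses the two factors; `pooled = TRUE`
#' computes one global median over both conditions instead.
#'
#' @param table a trial table after [exclude_trials()] with alpha power
#'   attached (only `rt`, `condition`, `included` are used here).
#' @param pooled use a single median over all included trials.
#' @return the table with `speed_bin` in {fast, slow} for included trials,
#'   "unassigned" otherwise.
#' @export
median_split <- function(table, pooled = FALSE) {
  stopifnot(!is.null(table$included))
  table$speed_bin <- "unassigned"
  groups <- if (pooled) list(all = which(table$included))
    else split(which(table$included), table$condition[table$included])
  for (idx in groups) {
    if (length(idx) < 4)
      stop("median split needs at least 4 included trials per condition")
    rt <- table$rt[idx]
    if (max(rt) == min(rt))
      stop("degenerate median split: all RTs identical")
    med <- stats::median(rt)
    table$speed_bin[idx] <- ifelse(rt < med, "fast", "slow")
  }
  table
}

#' Mean alpha power in fast and slow bins
#'
#' Per condition, the mean prestimulus alpha power over fast and over slow
#' trials and their difference (slow minus fast).
#'
#' @param table a trial table after [median_split()] with `alpha_power`.
#' @return data.frame: condition, alpha_fast, alpha_slow, alpha_diff,
#'   n_fast, n_slow.
#' @export
speed_bin_power <- function(table) {
  stopifnot(!is.null(table$alpha_power), !is.null(table$speed_bin))
  conds <- unique(table$condition)
  out <- lapply(conds, function(cn) {
    f <- table$condition == cn & table$speed_bin == "fast"
    s <- table$condition == cn & table$speed_bin == "slow"
    if (!any(f) || !any(s)) stop("empty speed bin in condition ", cn)
    data.frame(condition = cn,
               alpha_fast = mean(table$alpha_power[f]),
               alpha_slow = mean(table$alpha_power[s]),
               alpha_diff = mean(table$alpha_power[s]) -
                 mean(table$alpha_power[f]),
               n_fast = sum(f), n_slow = sum(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman rank correlation
#'
#' Rank-based correlation: both vectors are converted to ranks (average
#' ranks for ties) and the Pearson correlation of the ranks is returned.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop("need two equal-length vectors of at least 4 values")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) stop("zero variance in a rank vector")
  sum(dx * dy) / (sx * sy)
}

#' Fisher z transform of a correlation coefficient
#'
#' z = 0.5 * ln((1 + r) / (1 - r)). Coefficients at +/-1 are an error by
#' default; with `clamp = TRUE` they are clamped to +/-(1 - 1e-7) first
#' (for degenerate simulated subjects), never silently.
#'
#' @param rho correlation coefficient(s) with |rho| < 1.
#' @param clamp clamp |rho| >= 1 instead of failing.
#' @return z score(s).
#' @export
fisher_z <- function(rho, clamp = FALSE) {
  if (any(abs(rho) >= 1)) {
    if (!clamp) stop("|rho| >= 1: Fisher z undefined (set clamp = TRUE ",
                     "to clamp at 1 - 1e-7)")
    rho <- pmin(pmax(rho, -(1 - 1e-7)), 1 - 1e-7)
  }
  0.5 * log((1 + rho) / (1 - rho))
}

#' Per-subject alpha-RT coupling summary
#'
#' For each condition: the Spearman correlation between single-trial
#' prestimulus alpha power and RT over all included trials (both speed bins
#' pooled), its Fisher z score, and the fast/slow bin means from
#' [speed_bin_power()].
#'
#' @param table a trial table after [median_split()] with `alpha_power`.
#' @param clamp passed to [fisher_z()].
#' @return data.frame: subject, group, condition, rho, z, alpha_fast,
#'   alpha_slow, alpha_diff, n_trials.
#' @export
subject_coupling <- function(table, clamp = FALSE) {
  bins <- speed_bin_power(table)
  out <- lapply(seq_len(nrow(bins)), function(i) {
    cn <- bins$condition[i]
    inc <- table$condition == cn & table$included
    rho <- spearman_rho(table$alpha_power[inc], table$rt[inc])
    data.frame(subject = table$subject[1] %||% NA,
               group = table$group[1] %||% NA,
               condition = cn, rho = rho, z = fisher_z(rho, clamp = clamp),
               alpha_fast = bins$alpha_fast[i], alpha_slow = bins$alpha_slow[i],
               alpha_diff = bins$alpha_diff[i],
               n_trials = sum(inc), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
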