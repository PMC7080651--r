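#' Mixed-design (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate mixed-model decomposition for one between-subjects
#' factor crossed with one or more within-subjects factors on a balanced
#' design (every subject observed in every within-cell): subjects random,
#' factors fixed, computed through `aov` error strata. For every effect
#' involving a within factor, the Greenhouse-Geisser epsilon is estimated
#' from the pooled within-group covariance of the subject x cell matrix
#' (box epsilon on the orthonormalized effect contrasts) and the corrected
#' p-value uses epsilon-scaled degrees of freedom. Effects whose within
#' part has a single degree of freedom (all 2-level factors here) have
#' epsilon = 1 identically, so corrected and uncorrected p coincide.
#' Partial eta squared is SS_effect / (SS_effect + SS_error) with the error
#' term of the effect's own stratum.
#'
#' @param data long data.frame with one row per subject x within-cell.
#' @param dv name of the value column.
#' @param between name of the between-subjects factor (or NULL for a fully
#'   within design).
#' @param within character vector of within-subjects factor names.
#' @param subject name of the subject identifier column.
#' @return data.frame with effect, df_num, df_den, F, epsilon, p_gg,
#'   partial_eta_sq (class `anova_table`).
#' @export
mixed_anova <- function(data, dv = "value", between = "group",
                        within, subject = "subject") {
  data <- as.data.frame(data)
  for (v in c(between, within, subject))
    data[[v]] <- factor(data[[v]])
  if (!is.null(between) && nlevels(data[[between]]) < 2)
    between <- NULL                 # single stratum: fully within design
  cells <- interaction(data[within], drop = TRUE)
  tab <- table(data[[subject]], cells)
  if (any(tab != 1))
    stop("design must be balanced: one observation per subject and within-cell")

  ss_tot <- sum((data[[dv]] - mean(data[[dv]]))^2)
  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject, "/(",
                paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(form, data = data)
  sm <- summary(fit)

  eps <- gg_epsilons(data, dv, between, within, subject)
  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    terms <- trimws(rownames(st))
    resid <- which(terms == "Residuals")
    if (!length(resid)) next
    ss_err <- st[resid, "Sum Sq"]; df_err <- st[resid, "Df"]
    for (i in seq_len(nrow(st))[-resid]) {
      ss <- st[i, "Sum Sq"]; df1 <- st[i, "Df"]
      f <- if (ss_tot == 0 || ss <= 1e-10 * ss_tot) 0
        else (ss / df1) / (ss_err / df_err)
      eff <- terms[i]
      e <- eps[[canonical_effect(eff, within)]] %||% 1
      p <- if (f == 0) 1 else stats::pf(f, e * df1, e * df_err,
                                        lower.tail = FALSE)
      rows[[length(rows) + 1]] <-
        data.frame(effect = eff, df_num = df1, df_den = df_err, F = f,
                   epsilon = e, p_gg = p,
                   partial_eta_sq = if (ss + ss_err > 0) ss / (ss + ss_err)
                     else 0,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("anova_table", class(out))
  out
}

# the within-factor part of an effect name, in canonical order
canonical_effect <- function(effect, within) {
  parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
  w <- within[within %in% parts]
  if (!length(w)) NA_character_ else paste(w, collapse = ":")
}

# box (Greenhouse-Geisser) epsilon for every within-effect, from the pooled
# within-group covariance of the subject x cell matrix
gg_epsilons <- function(data, dv, between, within, subject) {
  cells <- interaction(data[within], drop = TRUE, lex.order = TRUE)
  y <- tapply(data[[dv]], list(data[[subject]], cells), mean)
  grp <- if (is.null(between)) rep(1, nrow(y)) else
    data[[between]][match(rownames(y), data[[subject]])]
  centered <- y
  for (g in unique(grp)) {
    i <- grp == g
    centered[i, ] <- sweep(y[i, , drop = FALSE], 2,
                           colMeans(y[i, , drop = FALSE]))
  }
  n_eff <- nrow(y) - length(unique(grp))
  S <- crossprod(centered) / max(n_eff, 1)

  lv <- lapply(data[within], function(f) nlevels(factor(f)))
  eff_sets <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, paste, collapse = ":", simplify = FALSE)),
    use.names = FALSE)
  eps <- list()
  for (eff in eff_sets) {
    parts <- strsplit(eff, ":")[[1]]
    M <- matrix(1, 1, 1)
    for (w in within) {          # lex.order = TRUE: first factor varies slowest
      k <- lv[[w]]
      B <- if (w %in% parts) t(stats::contr.helmert(k)) else
        matrix(1 / k, 1, k)
      M <- kronecker(M, B)
    }
    M <- t(qr.Q(qr(t(M))))       # orthonormal rows
    d <- nrow(M)
    Tm <- M %*% S %*% t(M)
    tr <- sum(diag(Tm)); tr2 <- sum(Tm * Tm)
    eps[[eff]] <- if (d == 1 || tr2 <= 0) 1
      else max(min(tr^2 / (d * tr2), 1), 1 / d)
  }
  eps
}

#' @export
print.anova_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$F <- round(df$F, 3); df$epsilon <- round(df$epsilon, 3)
  df$p_gg <- signif(df$p_gg, 3)
  df$partial_eta_sq <- round(df$partial_eta_sq, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected pairwise contrasts
#'
#' Runs a paired or independent t-test per contrast and multiplies raw
#' p-values by the family size (capped at 1). Cohen's d is the mean
#' difference over the SD of differences (paired) or over the pooled SD
#' (independent).
#'
#' @param contrasts list of contrasts; each a list with `x`, `y` (numeric
#'   vectors), `paired` (logical), and optionally `name`.
#' @return data.frame: name, estimate, t, df, p_raw, p_bonferroni, cohens_d.
#' @export
posthoc_pairwise <- function(contrasts) {
  m <- length(contrasts)
  if (!m) stop("empty contrast family")
  rows <- lapply(seq_len(m), function(i) {
    ct <- contrasts[[i]]
    r <- if (isTRUE(ct$paired)) {
      d <- ct$x - ct$y
      tt <- stats::t.test(ct$x, ct$y, paired = TRUE)
      list(est = mean(d), d = mean(d) / stats::sd(d), tt = tt)
    } else {
      tt <- stats::t.test(ct$x, ct$y, var.equal = TRUE)
      list(est = mean(ct$x) - mean(ct$y),
           d = cohens_d_pooled(ct$x, ct$y), tt = tt)
    }
    data.frame(name = ct$name %||% paste0("contrast_", i),
               estimate = r$est, t = unname(r$tt$statistic),
               df = unname(r$tt$parameter), p_raw = r$tt$p.value,
               p_bonferroni = min(1, m * r$tt$p.value),
               cohens_d = r$d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

cohens_d_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Independent-samples t-test with pooled-SD Cohen's d
#'
#' Two-sample t with pooled variance (df = n_x + n_y - 2) and
#' Cohen's d = (mean_x - mean_y) / pooled SD.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return data.frame: estimate, t, df, p, cohens_d.
#' @export
independent_t_d <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) + stats::var(y) == 0) stop("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  data.frame(estimate = mean(x) - mean(y), t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             cohens_d = cohens_d_pooled(x, y))
}

#' Per-group Pearson correlations between features and test scores
#'
#' For each group separately (no cross-group pooling, to avoid the
#' between-group mean differences driving the correlations), the Pearson r
#' and two-sided p for every (feature, test) pair, aligned by subject.
#'
#' @param features data.frame with `subject` plus numeric feature columns.
#' @param scores data.frame with `subject`, `group` plus numeric test
#'   columns.
#' @param feature_cols,score_cols columns to correlate (defaults: all
#'   numeric columns of each table).
#' @return data.frame: group, feature, test, r, p, n.
#' @export
feature_neuropsych_corr <- function(features, scores,
                                    feature_cols = NULL, score_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   TRUE)], "subject")
  if (is.null(score_cols))
    score_cols <- setdiff(names(scores)[vapply(scores, is.numeric, TRUE)],
                          "subject")
  merged <- merge(features, scores, by = "subject")
  rows <- list()
  for (g in unique(merged$group)) {
    sub <- merged[merged$group == g, ]
    if (nrow(sub) < 3) stop("fewer than 3 subjects in group ", g)
    for (fc in feature_cols) for (sc in score_cols) {
      ct <- stats::cor.test(sub[[fc]], sub[[sc]], method = "pearson")
      rows[[length(rows) + 1]] <-
        data.frame(group = g, feature = fc, test = sc,
                   r = unname(ct$estimate), p = ct$p.value, n = nrow(sub),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
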