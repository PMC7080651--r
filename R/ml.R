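#' Min-max rescale features to 0-1 using a fitting subset
#'
#' Per feature, (x - min) / (max - min) with min and max taken from the
#' `fit_on` rows only; the transform is then applied to all rows, so rows
#' outside the fitted range map outside [0, 1] (by design: in
#' cross-validation the scaler is fitted on training rows and applied
#' unchanged to test rows).
#'
#' @param x numeric matrix or data.frame of features.
#' @param fit_on row indices the scaler is fitted on (default all rows).
#' @return list with `x` (rescaled matrix) and `scaler` (data.frame of
#'   per-feature min and max).
#' @export
rescale01 <- function(x, fit_on = seq_len(nrow(x))) {
  x <- as.matrix(x)
  mn <- apply(x[fit_on, , drop = FALSE], 2, min)
  mx <- apply(x[fit_on, , drop = FALSE], 2, max)
  if (any(mx - mn == 0))
    stop("constant feature in fitting rows: ",
         paste(colnames(x)[mx - mn == 0], collapse = ", "))
  list(x = sweep(sweep(x, 2, mn), 2, mx - mn, "/"),
       scaler = data.frame(feature = colnames(x), min = mn, max = mx,
                           row.names = NULL))
}

#' Hyperparameter grid for the RBF-kernel SVM
#'
#' The standard coarse search lattice: cost C over powers of two from
#' 2^-5 to 2^15 and kernel width g over 2^-15 to 2^3 (step 2^2).
#'
#' @param c_exp,g_exp exponents of 2 for C and g.
#' @return data.frame with columns C and g, one row per combination.
#' @export
svm_grid <- function(c_exp = seq(-5, 15, by = 2),
                     g_exp = seq(-15, 3, by = 2)) {
  expand.grid(C = 2^c_exp, g = 2^g_exp)
}

#' Enumerate candidate feature subsets
#'
#' All non-empty subsets of `features` up to `max_size` members, ordered by
#' size (so the smaller-subset tie-break is a first-hit rule).
#'
#' @param features character vector of feature names.
#' @param max_size largest subset size enumerated.
#' @return list of character vectors.
#' @export
feature_subsets <- function(features, max_size = 2) {
  max_size <- min(max_size, length(features))
  unlist(lapply(seq_len(max_size), function(k)
    utils::combn(features, k, simplify = FALSE)), recursive = FALSE)
}

#' Confusion-matrix metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN), accuracy (TP+TN)/total. A zero denominator yields NA
#' (undefined), never 0.
#'
#' @param tp,fp,fn,tn non-negative counts, total > 0.
#' @return named list of the five rates.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = rate(tp, tp + fn), specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
       accuracy = (tp + tn) / (tp + fp + fn + tn))
}

#' Rank-based ROC AUC
#'
#' The probability that a random positive outranks a random negative, with
#' ties counted one half — the Mann-Whitney statistic computed from average
#' ranks of the decision scores.
#'
#' @param scores numeric decision values (larger = more positive).
#' @param labels logical or two-level vector; `TRUE` / second level /
#'   `positive` marks the positive class.
#' @param positive value of `labels` marking positives (default `TRUE` for
#'   logical labels, last level otherwise).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (is.null(positive))
    positive <- if (is.logical(labels)) TRUE else
      utils::tail(sort(unique(as.character(labels))), 1)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: each class dealt round-robin into k folds
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- sample(which(labels == cl))
    fold[i] <- rep_len(sample(k), length(i))
  }
  fold
}

plain_folds <- function(n, k) {
  sample(rep_len(sample(k), n))
}

svm_fit <- function(x, y, C, g, regression = FALSE) {
  e1071::svm(x = x, y = y, type = if (regression) "eps-regression"
               else "C-classification",
             kernel = "radial", cost = C, gamma = g, scale = FALSE)
}

# inner k-fold score for one (subset, C, g): mean accuracy or negative MSE
inner_cv_score <- function(x, y, subset, C, g, fold, regression) {
  k <- max(fold)
  score <- 0; n <- 0
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te) || (!regression && length(unique(y[tr])) < 2)) next
    fit <- svm_fit(x[tr, subset, drop = FALSE], y[tr], C, g, regression)
    pred <- stats::predict(fit, x[te, subset, drop = FALSE])
    score <- score + if (regression) -sum((as.numeric(pred) - y[te])^2)
      else sum(pred == y[te])
    n <- n + sum(te)
  }
  score / n
}

# pick the best (subset, C, g) by inner CV; ties go to the first hit, and
# candidates are ordered smaller subset, then smaller C, then smaller g
select_model <- function(x, y, grid, subsets, k, regression) {
  fold <- if (regression) plain_folds(length(y), k) else
    stratified_folds(y, k)
  grid <- grid[order(grid$C, grid$g), , drop = FALSE]
  best <- NULL; best_score <- -Inf
  for (s in subsets) for (i in seq_len(nrow(grid))) {
    sc <- inner_cv_score(x, y, s, grid$C[i], grid$g[i], fold, regression)
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best <- list(subset = s, C = grid$C[i], g = grid$g[i])
    }
  }
  best
}

#' Nested cross-validated SVM classification
#'
#' The full protocol: for each repetition, subjects are split into k
#' stratified outer folds; inside every outer training set an inner
#' stratified k-fold evaluates every (feature subset, C, g) combination and
#' the combination with the best inner accuracy (ties broken toward the
#' smaller subset, then smaller C, then smaller g) is refit on the whole
#' outer training set and applied to the held-out fold. Feature rescaling
#' to 0-1 is fitted strictly on the outer training rows. Per repetition
#' the outer-fold predictions are pooled into one confusion matrix and one
#' ROC curve; aggregates are means with percentile (2.5/97.5) 95% CIs over
#' repetitions.
#'
#' `leak = TRUE` deliberately breaks the protocol (rescaling fitted on all
#' subjects and the feature subset chosen once on the full data before the
#' outer loop) to demonstrate the optimistic bias of leakage; it exists for
#' that demonstration only.
#'
#' @param x numeric feature matrix (subjects x features, named columns).
#' @param y class labels (two levels; the lexicographically last level is
#'   treated as positive for sensitivity/PPV).
#' @param grid data.frame of C, g candidates ([svm_grid()]).
#' @param subsets list of feature-name subsets ([feature_subsets()]).
#' @param k folds (outer and inner).
#' @param reps repetitions of the whole outer CV.
#' @param seed RNG seed.
#' @param leak fit the scaler and choose the subset on all data (leaky).
#' @return a `cv_report`: list with `per_rep` (data.frame of per-repetition
#'   accuracy, auc, sensitivity, specificity, ppv, npv), `aggregate`
#'   (mean, ci_lo, ci_hi per metric), `selected` (data.frame of per-fold
#'   selections), `seed`.
#' @export
nested_cv_classify <- function(x, y, grid = svm_grid(),
                               subsets = feature_subsets(colnames(x), 1),
                               k = 10, reps = 100, seed = 1, leak = FALSE) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nlevels(y) == 2, nrow(grid) > 0, length(subsets) > 0)
  if (min(table(y)) < k)
    stop("need at least k subjects per class for stratified ", k, "-fold CV")
  positive <- levels(y)[2]
  set.seed(as.integer(seed))

  leak_scaled <- if (leak) rescale01(x)$x else NULL
  leak_model <- if (leak)
    select_model(leak_scaled, y, grid, subsets, k, regression = FALSE)

  per_rep <- vector("list", reps); selected <- list()
  for (r in seq_len(reps)) {
    fold <- stratified_folds(y, k)
    pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
    dec <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (!length(te)) next
      xs <- if (leak) leak_scaled else {
        sc <- rescale01(x, fit_on = tr); sc$x
      }
      mdl <- if (leak) leak_model else
        select_model(xs[tr, , drop = FALSE], y[tr], grid, subsets, k,
                     regression = FALSE)
      fit <- svm_fit(xs[tr, mdl$subset, drop = FALSE], y[tr],
                     mdl$C, mdl$g)
      pr <- stats::predict(fit, xs[te, mdl$subset, drop = FALSE],
                           decision.values = TRUE)
      pred[te] <- pr
      dvm <- attr(pr, "decision.values")
      # e1071 names the column "A/B": positive decision values favor A;
      # orient so larger always means the positive class
      first <- sub("/.*", "", colnames(dvm)[1])
      dec[te] <- if (first == positive) drop(dvm) else -drop(dvm)
      selected[[length(selected) + 1]] <-
        data.frame(rep = r, fold = f, C = mdl$C, g = mdl$g,
                   subset = paste(mdl$subset, collapse = "+"),
                   stringsAsFactors = FALSE)
    }
    tp <- sum(pred == positive & y == positive)
    fp <- sum(pred == positive & y != positive)
    fn <- sum(pred != positive & y == positive)
    tn <- sum(pred != positive & y != positive)
    m <- confusion_metrics(tp, fp, fn, tn)
    per_rep[[r]] <- data.frame(rep = r, accuracy = m$accuracy,
                               auc = roc_auc(dec, y, positive = positive),
                               sensitivity = m$sensitivity,
                               specificity = m$specificity,
                               ppv = m$ppv, npv = m$npv)
  }
  build_cv_report(do.call(rbind, per_rep), do.call(rbind, selected), seed)
}

#' Nested cross-validated SVM regression
#'
#' Same nesting as [nested_cv_classify()] with plain (unstratified) outer
#' and inner folds, inner selection by mean squared error, and the target
#' rescaled to 0-1 (scaler fitted on outer training rows). Per repetition
#' the pooled out-of-fold predictions yield MSE (on the rescaled target)
#' and two R-squared conventions: `r2` — the squared Pearson correlation
#' between predicted and observed (primary), and `r2_ss` — 1 - SSE/SST,
#' which can be negative out of sample.
#'
#' @inheritParams nested_cv_classify
#' @param target numeric response vector.
#' @return a `cv_report` with per-repetition r2, r2_ss, mse.
#' @export
nested_cv_regress <- function(x, target, grid = svm_grid(),
                              subsets = feature_subsets(colnames(x), 1),
                              k = 10, reps = 100, seed = 1) {
  x <- as.matrix(x)
  stopifnot(length(target) == nrow(x), nrow(grid) > 0, length(subsets) > 0)
  if (stats::sd(target) == 0) stop("constant regression target")
  set.seed(as.integer(seed))

  per_rep <- vector("list", reps); selected <- list()
  for (r in seq_len(reps)) {
    fold <- plain_folds(length(target), k)
    pred <- numeric(length(target))
    y01 <- numeric(length(target))
    for (f in seq_len(max(fold))) {
      tr <- which(fold != f); te <- which(fold == f)
      if (!length(te)) next
      sc <- rescale01(x, fit_on = tr)
      ymn <- min(target[tr]); ymx <- max(target[tr])
      if (ymx == ymn) stop("constant target in a training fold")
      yt <- (target - ymn) / (ymx - ymn)
      mdl <- select_model(sc$x[tr, , drop = FALSE], yt[tr], grid, subsets,
                          k, regression = TRUE)
      fit <- svm_fit(sc$x[tr, mdl$subset, drop = FALSE], yt[tr],
                     mdl$C, mdl$g, regression = TRUE)
      pred[te] <- as.numeric(stats::predict(fit,
                                            sc$x[te, mdl$subset,
                                                 drop = FALSE]))
      y01[te] <- yt[te]
      selected[[length(selected) + 1]] <-
        data.frame(rep = r, fold = f, C = mdl$C, g = mdl$g,
                   subset = paste(mdl$subset, collapse = "+"),
                   stringsAsFactors = FALSE)
    }
    mse <- mean((pred - y01)^2)
    r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, y01)^2
    r2_ss <- 1 - sum((pred - y01)^2) / sum((y01 - mean(y01))^2)
    per_rep[[r]] <- data.frame(rep = r, r2 = r2, r2_ss = r2_ss, mse = mse)
  }
  build_cv_report(do.call(rbind, per_rep), do.call(rbind, selected), seed)
}

build_cv_report <- function(per_rep, selected, seed) {
  metrics <- setdiff(names(per_rep), "rep")
  agg <- do.call(rbind, lapply(metrics, function(m) {
    v <- per_rep[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               ci_lo = unname(stats::quantile(v, 0.025, na.rm = TRUE)),
               ci_hi = unname(stats::quantile(v, 0.975, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_rep = per_rep, aggregate = agg, selected = selected,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d repetitions (seed %s)\n", nrow(x$per_rep),
              format(x$seed)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", agg$metric[i],
                agg$mean[i], agg$ci_lo[i], agg$ci_hi[i]))
  top <- sort(table(x$selected$subset), decreasing = TRUE)
  cat("  most selected subset:", names(top)[1],
      sprintf("(%d/%d folds)\n", top[1], nrow(x$selected)))
  invisible(x)
}
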