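test_that("rescale01 maps the fitting rows onto [0, 1] and extrapolates", {
  x <- matrix(c(2, 4, 6), dimnames = list(NULL, "f"))
  expect_equal(as.numeric(rescale01(x)$x), c(0, 0.5, 1))
  # fit on {0, 10}, transform 15 -> 1.5
  x2 <- matrix(c(0, 10, 15), dimnames = list(NULL, "f"))
  expect_equal(rescale01(x2, fit_on = 1:2)$x[3], 1.5)
  # idempotence on a min/max-spanning [0, 1] feature
  x3 <- matrix(c(0, 0.3, 1), dimnames = list(NULL, "f"))
  expect_equal(rescale01(x3)$x, x3)
  expect_error(rescale01(matrix(rep(1, 3), dimnames = list(NULL, "f"))),
               "constant feature")
})

test_that("confusion metrics satisfy their defining identities", {
  m <- confusion_metrics(9, 2, 1, 8)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 9 / 11)
  expect_equal(m$npv, 8 / 9)
  expect_equal(m$accuracy, 0.85)
  perfect <- confusion_metrics(5, 0, 0, 5)
  expect_true(all(unlist(perfect) == 1))
  # degenerate: no positives at all -> sensitivity undefined, not 0
  none <- confusion_metrics(0, 3, 0, 7)
  expect_true(is.na(none$sensitivity))
  expect_false(is.na(none$specificity))
})

test_that("rank-based AUC equals the exhaustive pair-counting oracle", {
  # perfectly ordered scores
  expect_equal(roc_auc(1:6, c(F, F, F, T, T, T)), 1)
  expect_equal(roc_auc(6:1, c(F, F, F, T, T, T)), 0)
  # handcrafted set with a tie across classes
  s <- c(0.1, 0.4, 0.4, 0.8, 0.2, 0.9)
  l <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  expect_equal(roc_auc(s, l), pair_count_auc(s, l))
  set.seed(6)
  for (i in 1:15) {
    sc <- round(rnorm(12), 1)            # rounding induces ties
    lb <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), pair_count_auc(sc, lb))
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC agrees with pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- rnorm(40)
  lb <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  expect_equal(roc_auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
  expect_equal(roc_auc(exp(sc), lb), roc_auc(sc, lb))
  expect_equal(roc_auc(rank(sc), lb), roc_auc(sc, lb))
})

small_grid <- svm_grid(c(-1, 3, 7), c(-5, -1, 3))

test_that("nested CV reaches near-perfect accuracy on separable classes", {
  set.seed(21)
  n <- 40
  y <- rep(c("HC", "MCI"), each = n / 2)
  x <- cbind(sep = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 5, 0.3)),
             noise = rnorm(n))
  rep_out <- nested_cv_classify(x, y, grid = small_grid,
                                subsets = feature_subsets(colnames(x), 1),
                                k = 5, reps = 3, seed = 77)
  acc <- rep_out$aggregate$mean[rep_out$aggregate$metric == "accuracy"]
  expect_gte(acc, 0.99)
  auc <- rep_out$aggregate$mean[rep_out$aggregate$metric == "auc"]
  expect_gte(auc, 0.99)
  # the informative feature is the one selected
  sel <- rep_out$selected$subset
  expect_gt(mean(sel == "sep"), 0.5)
})

test_that("nested CV accuracy is at chance for permuted labels", {
  set.seed(31)
  n <- 56
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- sample(rep(c("HC", "MCI"), each = n / 2))
  rep_out <- nested_cv_classify(x, y, grid = small_grid,
                                subsets = feature_subsets(colnames(x), 1),
                                k = 10, reps = 5, seed = 13)
  acc <- rep_out$aggregate$mean[rep_out$aggregate$metric == "accuracy"]
  expect_lt(abs(acc - 0.5), 0.10)
})

test_that("nested CV is reproducible under a fixed seed", {
  set.seed(99)
  n <- 24
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rep(c("HC", "MCI"), each = n / 2)
  r1 <- nested_cv_classify(x, y, grid = small_grid, k = 4, reps = 2,
                           seed = 5)
  r2 <- nested_cv_classify(x, y, grid = small_grid, k = 4, reps = 2,
                           seed = 5)
  expect_identical(r1$per_rep, r2$per_rep)
  expect_identical(r1$selected, r2$selected)
})

test_that("metric identities hold on every repetition", {
  set.seed(55)
  n <- 30
  x <- cbind(a = rnorm(n) + rep(c(0, 1), each = n / 2), b = rnorm(n))
  y <- rep(c("HC", "MCI"), each = n / 2)
  rep_out <- nested_cv_classify(x, y, grid = small_grid, k = 5, reps = 4,
                                seed = 3)
  pr <- rep_out$per_rep
  # reconstruct counts from the rates: with 15 positives and 15 negatives
  tp <- pr$sensitivity * 15; tn <- pr$specificity * 15
  expect_equal(pr$accuracy, (tp + tn) / n, tolerance = 1e-12)
  expect_true(all(pr$ppv >= 0 & pr$ppv <= 1, na.rm = TRUE))
  expect_true(all(pr$auc >= 0 & pr$auc <= 1))
})

test_that("leaky preprocessing inflates null accuracy", {
  set.seed(41)
  n <- 30
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- sample(rep(c("HC", "MCI"), each = n / 2))
  clean <- nested_cv_classify(x, y, grid = small_grid,
                              subsets = feature_subsets(colnames(x), 1),
                              k = 5, reps = 4, seed = 11)
  leaky <- nested_cv_classify(x, y, grid = small_grid,
                              subsets = feature_subsets(colnames(x), 1),
                              k = 5, reps = 4, seed = 11, leak = TRUE)
  acc <- function(r) r$aggregate$mean[r$aggregate$metric == "accuracy"]
  expect_gt(acc(leaky), acc(clean))
})

test_that("nested CV regression recovers a linear signal and stays near zero on noise", {
  set.seed(61)
  n <- 40
  x <- cbind(s = runif(n), n1 = rnorm(n))
  target <- 3 + 10 * x[, "s"] + rnorm(n, 0, 0.05)
  rep_out <- nested_cv_regress(x, target, grid = small_grid,
                               subsets = feature_subsets(colnames(x), 1),
                               k = 5, reps = 3, seed = 7)
  r2 <- rep_out$aggregate$mean[rep_out$aggregate$metric == "r2"]
  expect_gte(r2, 0.9)
  mse <- rep_out$aggregate$mean[rep_out$aggregate$metric == "mse"]
  expect_lt(mse, 0.02)
  # independent target: low r2
  null_out <- nested_cv_regress(x, rnorm(n), grid = small_grid,
                                subsets = feature_subsets(colnames(x), 1),
                                k = 5, reps = 3, seed = 8)
  expect_lt(null_out$aggregate$mean[null_out$aggregate$metric == "r2"],
            0.25)
  expect_error(nested_cv_regress(x, rep(1, n)), "constant")
})

test_that("the mean predictor bounds regression MSE from above", {
  # predicting the training mean of a 0-1 rescaled target has MSE equal to
  # the target variance; the tuned model should not do worse on average
  set.seed(71)
  n <- 40
  x <- cbind(s = runif(n))
  target <- 5 * x[, "s"] + rnorm(n, 0, 0.2)
  rep_out <- nested_cv_regress(x, target, grid = small_grid, k = 5,
                               reps = 2, seed = 3)
  y01 <- (target - min(target)) / (max(target) - min(target))
  expect_lt(rep_out$aggregate$mean[rep_out$aggregate$metric == "mse"],
            var(y01))
})

test_that("feature subset enumeration is complete and size-capped", {
  s <- feature_subsets(c("a", "b", "c"), 2)
  expect_length(s, 6)
  expect_true(all(lengths(s) <= 2))
  expect_length(feature_subsets(letters[1:4], 10), 15)
})
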