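#!/usr/bin/env Rscript
# Nested cross-validated SVM stage on the features exported by
# 03_group_stats.R: RBF-kernel classification of HC vs MCI from all 15
# features, and regression of a neuropsychological score from the 9
# electrophysiological features. Feature rescaling and subset selection sit
# strictly inside each outer training fold. Reduced scale relative to the
# full protocol (5 repetitions, single-feature subsets, coarse grid) to run
# in a few minutes; k, reps, grid and subset cap are all arguments of
# nested_cv_classify()/nested_cv_regress().

suppressMessages(library(prealpha))

feat_file <- "results/group_stats/features.csv"
if (!file.exists(feat_file))
  stop("run analysis/03_group_stats.R first (missing ", feat_file, ")")
feat <- read.csv(feat_file, stringsAsFactors = FALSE)
npsy <- read.csv("results/group_stats/neuropsych.csv",
                 stringsAsFactors = FALSE)

grid <- svm_grid(c(-1, 3, 7), c(-7, -3, 1))
fx <- as.matrix(feat[, feature_names()$all])
cvc <- nested_cv_classify(fx, feat$group, grid = grid,
                          subsets = feature_subsets(colnames(fx), 1),
                          k = 10, reps = 5, seed = 2027)
cat("HC vs MCI classification (nested 10-fold CV, 5 repetitions):\n")
print(cvc)

ex <- as.matrix(feat[, feature_names()$electrophysiological])
mmse <- npsy$MMSE[match(feat$subject, npsy$subject)]
cvr <- nested_cv_regress(ex, mmse, grid = grid,
                         subsets = feature_subsets(colnames(ex), 1),
                         k = 10, reps = 5, seed = 2028)
cat("\nMMSE regression from electrophysiological features:\n")
print(cvr)

dir.create("results/svm", showWarnings = FALSE, recursive = TRUE)
write.csv(cvc$per_rep, "results/svm/classification_reps.csv",
          row.names = FALSE)
write.csv(cvc$aggregate, "results/svm/classification.csv",
          row.names = FALSE)
write.csv(cvr$aggregate, "results/svm/regression_mmse.csv",
          row.names = FALSE)
cat("\ntables written to results/svm/\n")
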