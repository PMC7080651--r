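#' Restrict a recording to a time range
#' @param rec an `epoched_recording`. @param range ms pair (inclusive).
#' @return the cropped recording.
#' @export
subset_times <- function(rec, range) {
  idx <- which(rec$times >= range[1] & rec$times <= range[2])
  if (!length(idx)) stop("empty time range")
  rec$data <- rec$data[, , idx, drop = FALSE]
  rec$times <- rec$times[idx]
  rec
}

#' Restrict a recording to a channel subset
#' @param rec an `epoched_recording`. @param channels names to keep.
#' @return the restricted recording.
#' @export
subset_channels <- function(rec, channels) {
  idx <- match(channels, rec$channel_names)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  rec$data <- rec$data[, idx, , drop = FALSE]
  rec$channel_names <- channels
  rec
}

#' Run the single-subject analysis chain
#'
#' Average re-reference, zero-phase 1-30 Hz FIR band-pass, prestimulus
#' baseline correction, trial exclusion (invalid / incorrect / artifact /
#' +/-2 SD RT outliers), windowed-Fourier spectrogram, prestimulus alpha
#' ROI power, per-condition fast/slow median split and alpha-RT coupling,
#' behavioral summary, and the 15-feature row. After re-referencing the
#' filter and spectrogram run on the ROI electrodes only (both operations
#' are per-channel and no downstream statistic touches other channels).
#'
#' @param rec an `epoched_recording`.
#' @param roi [alpha_roi()] definition.
#' @param lo,hi band-pass edges, Hz.
#' @param baseline_window baseline interval, ms.
#' @param rt_max response window end, ms.
#' @param pooled_split use the pooled-median variant of the split.
#' @param tf_engine spectrogram engine (see [wft_spectrogram()]).
#' @return list with `trial_table`, `behavioral`, `coupling`, `features`.
#' @export
process_subject <- function(rec, roi = alpha_roi(), lo = 1, hi = 30,
                            baseline_window = c(-2000, 0), rt_max = 2250,
                            pooled_split = FALSE,
                            tf_engine = "filterbank") {
  rec <- rereference_average(rec)
  occ <- subset_channels(rec, roi$electrodes)
  occ <- bandpass_fir(occ, lo = lo, hi = hi)
  occ <- baseline_correct(occ, window = baseline_window)
  # crop to the ROI plus the taper half-width on both sides: every segment
  # entering the ROI average is untouched, everything else is dead weight
  occ <- subset_times(occ, c(roi$t_min - 150, roi$t_max + 150))
  tf <- wft_spectrogram(occ, t_range = c(roi$t_min, roi$t_max),
                        freqs = seq(roi$f_min, roi$f_max, by = 1),
                        engine = tf_engine)
  tt <- rec$trial_table
  tt$alpha_power <- extract_alpha_power(tf, roi)
  tt <- exclude_trials(tt, rt_max = rt_max)
  tt <- median_split(tt, pooled = pooled_split)
  behavioral <- behavioral_summary(tt)
  coupling <- subject_coupling(tt, clamp = TRUE)
  list(trial_table = tt, behavioral = behavioral, coupling = coupling,
       features = subject_features(behavioral, coupling))
}

#' Declarative configuration for a full pipeline run
#'
#' @param sim a [sim_params()] object (its `seed` is overridden by `seed`).
#' @param roi [alpha_roi()] definition.
#' @param lo,hi,baseline_window,rt_max preprocessing constants.
#' @param pooled_split global- instead of per-condition-median split.
#' @param ml_enabled run the SVM stage.
#' @param ml_k,ml_reps folds and repetitions of the nested CV.
#' @param ml_grid hyperparameter grid ([svm_grid()]).
#' @param ml_max_subset_size cap on enumerated subset size.
#' @param ml_leak leaky-preprocessing variant flag (demonstration only).
#' @param regress_targets neuropsychological scores to predict (names from
#'   [neuropsych_defaults()]), or NULL to skip regression.
#' @param seed global seed; fans out deterministically to every stage.
#' @return a `pipeline_config` list with a `config_hash` field.
#' @export
pipeline_config <- function(sim = sim_params(), roi = alpha_roi(),
                            lo = 1, hi = 30,
                            baseline_window = c(-2000, 0), rt_max = 2250,
                            pooled_split = FALSE, ml_enabled = FALSE,
                            ml_k = 10, ml_reps = 10,
                            ml_grid = svm_grid(c(-1, 3, 7), c(-7, -3, 1)),
                            ml_max_subset_size = 1, ml_leak = FALSE,
                            regress_targets = NULL, seed = 1L) {
  cfg <- list(sim = sim, roi = roi, lo = lo, hi = hi,
              baseline_window = baseline_window, rt_max = rt_max,
              pooled_split = pooled_split, ml_enabled = ml_enabled,
              ml_k = ml_k, ml_reps = ml_reps, ml_grid = ml_grid,
              ml_max_subset_size = ml_max_subset_size, ml_leak = ml_leak,
              regress_targets = regress_targets, seed = as.integer(seed))
  cfg$sim$seed <- cfg$seed
  cfg$config_hash <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

# FNV-1a 32-bit hash of the serialized configuration (provenance tag)
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648 - 2^31 * (h >= 2^31)), b)
    h <- (as.numeric(h) %% 2^32 + 2^32) %% 2^32
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline
#'
#' Simulate the cohort, process every subject ([process_subject()]), then
#' group-level inference: 2x2 mixed ANOVAs (group x congruency) on RT, ER
#' and Fisher z, the 2x2x2 ANOVA (group x speed x congruency) on
#' prestimulus alpha power, group t-tests with Cohen's d on the fast/slow
#' alpha difference and on the mean Fisher z, per-group Pearson
#' correlations of the electrophysiological features with
#' neuropsychological scores, and (optionally) the nested-CV SVM stage.
#' Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list: behavioral, coupling, features, anovas,
#'   ttests, posthoc (fast-vs-slow simple effects per group), correlations,
#'   cv (classification/regression reports or NULL), config_hash, seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(config$sim)

  behavioral <- coupling <- features <- NULL
  for (id in names(cohort$recordings)) {
    res <- tryCatch(
      process_subject(cohort$recordings[[id]], roi = config$roi,
                      lo = config$lo, hi = config$hi,
                      baseline_window = config$baseline_window,
                      rt_max = config$rt_max,
                      pooled_split = config$pooled_split),
      error = function(e) stop("stage process_subject, subject ", id, ": ",
                               conditionMessage(e), call. = FALSE))
    b <- cbind(subject = id, group = res$coupling$group[1],
               res$behavioral, stringsAsFactors = FALSE)
    behavioral <- rbind(behavioral, b)
    coupling <- rbind(coupling, res$coupling)
    features <- rbind(features, res$features)
  }

  anovas <- list(
    rt = mixed_anova(long_behav(behavioral, "mean_rt"), dv = "value",
                     between = "group", within = "congruency"),
    er = mixed_anova(long_behav(behavioral, "er"), dv = "value",
                     between = "group", within = "congruency"),
    alpha = mixed_anova(long_alpha(coupling), dv = "value",
                        between = "group", within = c("speed", "congruency")),
    z = mixed_anova(data.frame(subject = coupling$subject,
                               group = coupling$group,
                               congruency = coupling$condition,
                               value = coupling$z),
                    dv = "value", between = "group", within = "congruency"))

  hc <- features$group == "HC"
  alphadiff <- rowMeans(features[, c("alphadiff_cong", "alphadiff_incong")])
  zmean <- rowMeans(features[, c("z_cong", "z_incong")])
  ttests <- rbind(
    cbind(measure = "alpha_diff",
          independent_t_d(alphadiff[hc], alphadiff[!hc])),
    cbind(measure = "fisher_z", independent_t_d(zmean[hc], zmean[!hc])))

  # simple effects of the speed x group interaction: paired fast-vs-slow
  # alpha within each group (one Bonferroni family of two contrasts)
  fastm <- rowMeans(features[, c("alpha_cong_fast", "alpha_incong_fast")])
  slowm <- rowMeans(features[, c("alpha_cong_slow", "alpha_incong_slow")])
  posthoc <- posthoc_pairwise(list(
    list(name = "HC_fast_vs_slow", x = fastm[hc], y = slowm[hc],
         paired = TRUE),
    list(name = "MCI_fast_vs_slow", x = fastm[!hc], y = slowm[!hc],
         paired = TRUE)))

  correlations <- feature_neuropsych_corr(
    features[, c("subject", feature_names()$electrophysiological)],
    cohort$neuropsych)

  cv <- list(classification = NULL, regression = NULL)
  if (config$ml_enabled) {
    fx <- as.matrix(features[, feature_names()$all])
    subsets <- feature_subsets(colnames(fx), config$ml_max_subset_size)
    cv$classification <- nested_cv_classify(
      fx, features$group, grid = config$ml_grid, subsets = subsets,
      k = config$ml_k, reps = config$ml_reps,
      seed = child_seed(config$seed, 9001), leak = config$ml_leak)
    if (!is.null(config$regress_targets)) {
      ex <- as.matrix(features[, feature_names()$electrophysiological])
      esub <- feature_subsets(colnames(ex), config$ml_max_subset_size)
      np <- cohort$neuropsych[match(features$subject,
                                    cohort$neuropsych$subject), ]
      cv$regression <- lapply(stats::setNames(config$regress_targets,
                                              config$regress_targets),
        function(tg) nested_cv_regress(ex, np[[tg]], grid = config$ml_grid,
                                       subsets = esub, k = config$ml_k,
                                       reps = config$ml_reps,
                                       seed = child_seed(config$seed, 9002)))
    }
  }

  structure(list(behavioral = behavioral, coupling = coupling,
                 features = features, neuropsych = cohort$neuropsych,
                 anovas = anovas, ttests = ttests, posthoc = posthoc,
                 correlations = correlations, cv = cv,
                 config_hash = config$config_hash, seed = config$seed),
            class = "run_report")
}

long_behav <- function(behavioral, what) {
  cols <- paste0(what, c("_cong", "_incong"))
  if (what == "mean_rt") cols <- c("mean_rt_cong", "mean_rt_incong")
  data.frame(subject = rep(behavioral$subject, 2),
             group = rep(behavioral$group, 2),
             congruency = rep(c("congruent", "incongruent"),
                              each = nrow(behavioral)),
             value = c(behavioral[[cols[1]]], behavioral[[cols[2]]]),
             stringsAsFactors = FALSE)
}

long_alpha <- function(coupling) {
  data.frame(subject = rep(coupling$subject, 2),
             group = rep(coupling$group, 2),
             congruency = rep(coupling$condition, 2),
             speed = rep(c("fast", "slow"), each = nrow(coupling)),
             value = c(coupling$alpha_fast, coupling$alpha_slow),
             stringsAsFactors = FALSE)
}

#' Export a run report to CSV tables plus a JSON bundle
#'
#' Writes tidy CSVs (behavioral.csv, coupling.csv, features.csv,
#' neuropsych.csv, anova_<name>.csv, ttests.csv, correlations.csv, and CV
#' tables when present) and `report.json` holding the same content with a
#' schema version, the config hash and the seed.
#'
#' @param report a `run_report`. @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_report <- function(report, dir) {
  required <- c("behavioral", "coupling", "features", "anovas", "ttests",
                "correlations")
  missing <- required[!vapply(required, function(f)
    !is.null(report[[f]]), TRUE)]
  if (length(missing))
    stop("report is missing section(s): ", paste(missing, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(report$behavioral, "behavioral.csv")
  wcsv(report$coupling, "coupling.csv")
  wcsv(report$features, "features.csv")
  if (!is.null(report$neuropsych)) wcsv(report$neuropsych, "neuropsych.csv")
  for (nm in names(report$anovas))
    wcsv(as.data.frame(report$anovas[[nm]]), paste0("anova_", nm, ".csv"))
  wcsv(report$ttests, "ttests.csv")
  if (!is.null(report$posthoc)) wcsv(report$posthoc, "posthoc.csv")
  wcsv(report$correlations, "correlations.csv")
  if (!is.null(report$cv$classification)) {
    wcsv(report$cv$classification$per_rep, "cv_classification_reps.csv")
    wcsv(report$cv$classification$aggregate, "cv_classification.csv")
  }
  json <- list(schema = "prealpha-report/1",
               config_hash = report$config_hash, seed = report$seed,
               behavioral = report$behavioral, coupling = report$coupling,
               features = report$features, neuropsych = report$neuropsych,
               anovas = lapply(report$anovas, as.data.frame),
               ttests = report$ttests, posthoc = report$posthoc,
               correlations = report$correlations,
               cv = report$cv[!vapply(report$cv, is.null, TRUE)])
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Re-read an exported report bundle
#' @param dir directory written by [export_report()].
#' @return the parsed `report.json` as a list of data.frames.
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
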