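#' Assemble the 15 per-subject features
#'
#' Six behavioral features (per-condition error rate and mean RT plus the
#' flanker effects on both) and nine electrophysiological features
#' (prestimulus alpha power per speed x congruency cell, its grand mean
#' over the four cells, the slow-minus-fast difference per condition, and
#' the Fisher z of the alpha-RT Spearman correlation per condition).
#'
#' @param behavioral one-row data.frame from [behavioral_summary()].
#' @param coupling two-row data.frame from [subject_coupling()].
#' @return one-row data.frame: subject, group, then the 15 features.
#' @export
subject_features <- function(behavioral, coupling) {
  cg <- coupling[coupling$condition == "congruent", ]
  ig <- coupling[coupling$condition == "incongruent", ]
  stopifnot(nrow(cg) == 1, nrow(ig) == 1)
  data.frame(
    subject = cg$subject, group = cg$group,
    er_cong = behavioral$er_cong, er_incong = behavioral$er_incong,
    rt_cong = behavioral$mean_rt_cong, rt_incong = behavioral$mean_rt_incong,
    flanker_er = behavioral$flanker_er, flanker_rt = behavioral$flanker_rt,
    alpha_cong_fast = cg$alpha_fast, alpha_cong_slow = cg$alpha_slow,
    alpha_incong_fast = ig$alpha_fast, alpha_incong_slow = ig$alpha_slow,
    alpha_grandmean = mean(c(cg$alpha_fast, cg$alpha_slow,
                             ig$alpha_fast, ig$alpha_slow)),
    alphadiff_cong = cg$alpha_diff, alphadiff_incong = ig$alpha_diff,
    z_cong = cg$z, z_incong = ig$z,
    stringsAsFactors = FALSE)
}

#' Names of the feature groups
#'
#' @return list with `behavioral` (6 names), `electrophysiological`
#'   (9 names; the only inputs to SVM regression), and `all` (15).
#' @export
feature_names <- function() {
  behav <- c("er_cong", "er_incong", "rt_cong", "rt_incong",
             "flanker_er", "flanker_rt")
  electro <- c("alpha_cong_fast", "alpha_cong_slow", "alpha_incong_fast",
               "alpha_incong_slow", "alpha_grandmean", "alphadiff_cong",
               "alphadiff_incong", "z_cong", "z_incong")
  list(behavioral = behav, electrophysiological = electro,
       all = c(behav, electro))
}
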