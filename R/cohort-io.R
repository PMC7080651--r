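#' Write a cohort to the on-disk layout
#'
#' One directory per subject containing `meta.json` (sampling rate, channel
#' names, time axis limits, group, cube shape), `data.bin` — the epoch cube
#' as little-endian 8-byte IEEE doubles with samples varying fastest, then
#' channels, then trials — and `trials.csv`; plus a cohort-level
#' `neuropsych.csv`.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$recordings)) {
    rec <- cohort$recordings[[id]]
    sd <- file.path(dir, id)
    dir.create(sd, showWarnings = FALSE)
    d <- dim(rec$data)
    meta <- list(subject = id, group = rec$trial_table$group[1],
                 fs = rec$fs, channels = rec$channel_names,
                 times_ms = c(min(rec$times), max(rec$times)),
                 shape = list(trials = d[1], channels = d[2],
                              samples = d[3]),
                 dtype = "float64-little-endian",
                 order = "samples fastest, then channels, then trials")
    jsonlite::write_json(meta, file.path(sd, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    con <- file(file.path(sd, "data.bin"), "wb")
    writeBin(as.vector(aperm(rec$data, c(3, 2, 1))), con,
             size = 8, endian = "little")
    close(con)
    utils::write.csv(rec$trial_table, file.path(sd, "trials.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$neuropsych, file.path(dir, "neuropsych.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from the on-disk layout
#'
#' @param dir directory produced by [write_cohort()].
#' @return list with `recordings` and `neuropsych`, as from
#'   [simulate_cohort()].
#' @export
read_cohort <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  recs <- list()
  for (sd in subs) {
    meta <- jsonlite::read_json(file.path(sd, "meta.json"),
                                simplifyVector = TRUE)
    n <- meta$shape$trials * meta$shape$channels * meta$shape$samples
    con <- file(file.path(sd, "data.bin"), "rb")
    v <- readBin(con, "double", n = n, size = 8, endian = "little")
    close(con)
    cube <- aperm(array(v, dim = c(meta$shape$samples, meta$shape$channels,
                                   meta$shape$trials)), c(3, 2, 1))
    dimnames(cube) <- list(NULL, meta$channels, NULL)
    tt <- utils::read.csv(file.path(sd, "trials.csv"),
                          stringsAsFactors = FALSE)
    times <- seq(meta$times_ms[1], meta$times_ms[2], by = 1000 / meta$fs)
    recs[[meta$subject]] <- new_recording(cube, meta$fs, times,
                                          meta$channels, tt)
  }
  list(recordings = recs,
       neuropsych = utils::read.csv(file.path(dir, "neuropsych.csv"),
                                    stringsAsFactors = FALSE))
}
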