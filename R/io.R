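#' Read / write ROI time-course tables
#'
#' CSV with one column per ROI and one row per scan; the repetition time is
#' carried as an attribute, not stored in the file.
#'
#' @param path file path.
#' @export
read_roi_ts <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}

#' @rdname read_roi_ts
#' @param ts scans x ROIs matrix.
#' @export
write_roi_ts <- function(ts, path) {
  write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-scan label series
#'
#' Single-column CSV with header `label`.
#'
#' @param path file path.
#' @export
read_labels <- function(path) {
  df <- read.csv(path)
  if (!"label" %in% names(df)) stop("label column missing")
  as.character(df$label)
}

#' @rdname read_labels
#' @param labels character label vector.
#' @export
write_labels <- function(labels, path) {
  write.csv(data.frame(label = as.character(labels)), path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort as a directory tree
#'
#' One sub-directory per subject containing `game_roits.csv`,
#' `game_labels.csv`, `sleep_roits.csv`, `hypnogram.txt`, `bandpower.csv`,
#' `seeds.csv`, `truth.json`, `record.json`, plus a master `cohort.json`
#' manifest at the root.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cohort$subjects, `[[`, "", "id")
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    write_roi_ts(s$game$roits, file.path(sd, "game_roits.csv"))
    write_labels(s$game$labels, file.path(sd, "game_labels.csv"))
    if (!is.null(s$sleep)) {
      write_roi_ts(s$sleep$roits, file.path(sd, "sleep_roits.csv"))
      write_hypnogram(s$sleep$hypnogram, file.path(sd, "hypnogram.txt"))
      bp <- cbind(time = s$sleep$bandpower$times, s$sleep$bandpower$log_power)
      write.csv(as.data.frame(bp), file.path(sd, "bandpower.csv"),
                row.names = FALSE)
      write.csv(as.data.frame(s$sleep$seeds), file.path(sd, "seeds.csv"),
                row.names = FALSE)
      jsonlite::write_json(s$sleep$truth, file.path(sd, "truth.json"),
                           digits = NA, auto_unbox = TRUE)
    }
    if (!is.null(s$record))
      jsonlite::write_json(s$record, file.path(sd, "record.json"),
                           digits = NA, auto_unbox = TRUE)
  }
  manifest <- list(subjects = ids,
                   won_game = vapply(cohort$subjects, `[[`, "", "won_game"),
                   tr = cohort$config$design$tr,
                   n_rois = ncol(cohort$patterns))
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read one subject directory written by [write_cohort()]
#'
#' @param dir subject directory path.
#' @return list with the same fields as a generated subject (minus the
#'   design object).
#' @export
read_subject <- function(dir) {
  out <- list(id = basename(dir))
  out$game <- list(roits = read_roi_ts(file.path(dir, "game_roits.csv")),
                   labels = read_labels(file.path(dir, "game_labels.csv")))
  sleep_f <- file.path(dir, "sleep_roits.csv")
  if (file.exists(sleep_f)) {
    bp <- read.csv(file.path(dir, "bandpower.csv"), check.names = FALSE)
    out$sleep <- list(
      roits = read_roi_ts(sleep_f),
      hypnogram = read_hypnogram(file.path(dir, "hypnogram.txt")),
      bandpower = structure(list(times = bp$time,
                                 log_power = as.matrix(bp[, -1L]),
                                 bands = eeg_bands()),
                            class = "band_power"),
      seeds = as.list(read.csv(file.path(dir, "seeds.csv"))),
      truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                  simplifyVector = TRUE))
  }
  rec_f <- file.path(dir, "record.json")
  if (file.exists(rec_f))
    out$record <- jsonlite::read_json(rec_f, simplifyVector = TRUE)
  out
}

#' Read a pipeline configuration file
#'
#' Accepts YAML or JSON; missing fields fall back to [default_config()].
#'
#' @param path file path.
#' @return full configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  modifyList(default_config(), cfg)
}
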