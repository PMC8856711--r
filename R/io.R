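# Readers and writers for the package's plain-text interchange formats:
# EEG as a delimited channel-by-time matrix with a JSON sidecar header,
# events as a BIDS-events-style TSV, SCR as a delimited time/conductance/
# valid table, trials and feature tables as tidy TSV, ground truth and
# provenance as JSON.

#' Write / read an EEG recording as delimited matrix + JSON header
#'
#' The samples are stored time-by-channel (one column per channel) as TSV
#' and the header (sampling rate, channel labels, participant) as a JSON
#' sidecar `<path>.json`; events go to a separate events TSV via
#' [write_events()].
#'
#' @param recording An `eeg_recording`.
#' @param path Path of the TSV matrix file.
#' @return `read_recording()` returns an `eeg_recording` (events empty
#'   unless supplied).
#' @export
write_recording <- function(recording, path) {
  mat <- t(recording$samples)
  colnames(mat) <- recording$labels
  readr::write_tsv(as_tibble(mat), path, progress = FALSE)
  jsonlite::write_json(
    list(rate = recording$rate, labels = recording$labels,
         n_samples = ncol(recording$samples),
         participant = recording$participant),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param events Optional events tibble (e.g. from [read_events()]
#'   converted to samples) to attach.
#' @export
read_recording <- function(path, events = tibble()) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(readr::read_tsv(path, show_col_types = FALSE,
                                   progress = FALSE))
  if (nrow(mat) != hdr$n_samples || !identical(colnames(mat), hdr$labels)) {
    abort("EEG header is inconsistent with the data shape or channel labels.")
  }
  samples <- t(mat)
  dimnames(samples) <- NULL
  new_recording(samples, hdr$rate, hdr$labels, events,
                hdr$participant %||% NA_integer_)
}

#' Write / read the trial event table (BIDS-events-style TSV)
#'
#' Columns: `onset_s`, `duration_s`, `block`, `trial`, `condition`,
#' `cue`, `congruency`.
#'
#' @param schedule A [build_schedule()] table.
#' @param path TSV path.
#' @param config The generating [cohort_config()] (for the picture
#'   duration).
#' @export
write_events <- function(schedule, path, config) {
  ev <- tibble(
    onset_s = schedule$onset_s,
    duration_s = config$timing$picture_ms / 1000,
    block = schedule$block,
    trial = schedule$trial,
    condition = schedule$condition,
    cue = schedule$cue,
    congruency = schedule$congruency,
    next_onset_s = schedule$next_onset_s
  )
  readr::write_tsv(ev, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param max_onset_s Optional recording duration; onsets beyond it raise
#'   an error naming the offending row.
#' @export
read_events <- function(path, max_onset_s = NULL) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("onset_s", "duration_s", "block", "trial", "condition", "cue", "congruency")
  if (!all(need %in% names(ev))) {
    abort(paste("Events file lacks required columns:",
                paste(setdiff(need, names(ev)), collapse = ", ")))
  }
  if (is.unsorted(ev$onset_s)) abort("Events must be sorted by onset.")
  if (!is.null(max_onset_s) && any(ev$onset_s > max_onset_s)) {
    bad <- which(ev$onset_s > max_onset_s)[1]
    abort(sprintf("Event row %d has onset %.3f s beyond the recording end (%.3f s).",
                  bad, ev$onset_s[bad], max_onset_s))
  }
  ev
}

#' Write / read a skin-conductance trace
#'
#' Delimited columns `time_s`, `conductance`, `valid`.
#'
#' @param trace An `scr_trace`.
#' @param path TSV path.
#' @export
write_scr <- function(trace, path) {
  readr::write_tsv(tibble(time_s = trace$time_s,
                          conductance = trace$conductance,
                          valid = trace$valid),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scr
#' @param rate Sampling rate in Hz; checked against the time column.
#' @param events Optional events tibble to attach.
#' @export
read_scr <- function(path, rate, events = tibble()) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) abort("SCR time axis must be strictly increasing.")
  if (abs(median(dt) - 1 / rate) > 1e-6) {
    abort("SCR time axis is inconsistent with the stated sampling rate.")
  }
  new_scr_trace(df$conductance, rate, events, as.logical(df$valid))
}

#' Write / read the tidy trial-behavior table
#' @param trials Trial records from [simulate_rt()].
#' @param path TSV path.
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (any(!is.na(tr$rt_ms) & tr$rt_ms <= 0)) abort("Reaction times must be positive.")
  tr
}

#' Write ground truth as JSON
#' @param truth A [sample_traits()] table.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
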