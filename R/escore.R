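#' Per-cell mean log reaction time
#'
#' Natural-log transforms each usable reaction time and averages per
#' participant-by-condition (optionally by-block) cell. Timeouts are
#' always excluded and counted; incorrect responses are retained by
#' default (set `exclude_errors = TRUE` to drop them).
#'
#' @param trials A trial table as produced by [simulate_rt()] (columns
#'   `participant`, `condition`, `rt_ms`, `timeout`, `correct`, and
#'   `block` if `by` includes it).
#' @param by Cell definition: `"condition"` or `c("condition", "block")`.
#' @param exclude_errors Drop incorrect-response trials from RT means.
#' @return A tibble with grouping columns, `log_rt` (log ms), `n_trials`,
#'   `n_timeouts`.
#' @export
rt_condition_means <- function(trials, by = "condition",
                               exclude_errors = FALSE) {
  usable <- !trials$timeout & !is.na(trials$rt_ms)
  if (exclude_errors) usable <- usable & !is.na(trials$correct) & trials$correct
  cells <- trials[usable, ] |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant", by)))) |>
    dplyr::summarise(log_rt = mean(log(.data$rt_ms)),
                     n_trials = dplyr::n(), .groups = "drop")
  timeouts <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant", by)))) |>
    dplyr::summarise(n_timeouts = sum(.data$timeout), .groups = "drop")
  out <- dplyr::left_join(timeouts, cells, by = c("participant", by))
  out$n_trials[is.na(out$n_trials)] <- 0L
  if (any(out$n_trials == 0)) {
    warn("Some RT cells have no usable trials; their values are NA.")
  }
  dplyr::select(out, dplyr::all_of(c("participant", by)),
                "log_rt", "n_trials", "n_timeouts")
}

#' E difference scores: condition response minus neutral response
#'
#' For each non-neutral emotion, `E = R_emotion - R_neutral` within each
#' participant (and within each block and/or channel cell when those
#' columns are present in `responses`), in the native units of the
#' modality (log ms for RT, log conductance units for SCR, microvolts for
#' ERP components). The neutral condition is the mandatory reference;
#' cells lacking it raise an error.
#'
#' @param responses A tibble with a `condition` column, a response value
#'   column, and any of `participant`, `block`, `channel` as cell keys.
#' @param value Name of the response value column.
#' @param modality Modality tag recorded in the output
#'   (`"RT"`, `"SCR"`, `"P300"`, `"LPP"`).
#' @return A tibble: cell keys, `modality`, `emotion`, `value` (the E
#'   score).
#' @export
#' @examples
#' r <- tibble::tibble(participant = 1,
#'                     condition = c("neutral", "erotic"),
#'                     log_rt = c(2.3, 2.5))
#' escore(r, "log_rt", "RT")
escore <- function(responses, value, modality) {
  modality <- match.arg(modality, c("RT", "SCR", "P300", "LPP"))
  keys <- intersect(c("participant", "channel", "block", "half"), names(responses))
  wide <- responses |>
    dplyr::select(dplyr::all_of(c(keys, "condition", value))) |>
    tidyr::pivot_wider(names_from = "condition", values_from = dplyr::all_of(value))
  if (!"neutral" %in% names(wide) || anyNA(wide$neutral)) {
    abort("The neutral reference condition is missing; E scores are undefined without it.")
  }
  emotions <- intersect(EMOTIONS_NONNEUTRAL, names(wide))
  purrr::map_dfr(emotions, function(emo) {
    dplyr::bind_cols(
      wide[keys],
      tibble(modality = modality, emotion = emo,
             value = wide[[emo]] - wide$neutral)
    )
  })
}

#' Assign facilitated/impeded group labels from RT difference scores
#'
#' Strict sign rule: a participant is `facilitated` in an emotion
#' condition when `E_RT < 0` (faster than neutral), `impeded` when
#' `E_RT > 0`, and `undefined` when exactly zero; undefined participants
#' are excluded from classification with a warning. Group sizes are
#' reported in the `groups` attribute.
#'
#' @param e_rt An [escore()] table for the RT modality (one row per
#'   participant and emotion).
#' @return A tibble: `participant`, `emotion`, `label`.
#' @export
assign_groups <- function(e_rt) {
  out <- tibble(
    participant = e_rt$participant,
    emotion = e_rt$emotion,
    label = dplyr::case_when(
      is.na(e_rt$value) ~ NA_character_,
      e_rt$value < 0 ~ "facilitated",
      e_rt$value > 0 ~ "impeded",
      TRUE ~ "undefined"
    )
  )
  if (any(out$label == "undefined", na.rm = TRUE)) {
    warn("Some participants have E_RT exactly 0; labelled `undefined` and excluded from classification.")
  }
  attr(out, "groups") <- dplyr::count(out, .data$emotion, .data$label)
  out
}
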