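#' Simulate reaction times for one participant
#'
#' Log reaction time is additive: a participant baseline, the cue effect
#' (spatial < center < none by default), the flanker congruency effect
#' (congruent < incongruent), the planted per-emotion effect from the
#' ground truth, and Gaussian residual noise; the result is exponentiated
#' to milliseconds. Responses slower than the deadline are recorded as
#' timeouts (missing RT, no response). A small configurable fraction of
#' responses is marked incorrect.
#'
#' @inheritParams simulate_eeg
#' @return A tibble of trial records: `participant`, `trial`, `block`,
#'   `condition`, `cue`, `congruency`, `rt_ms` (NA on timeout), `timeout`,
#'   `correct`.
#' @export
simulate_rt <- function(truth, schedule, config, participant = 1L) {
  validate_cohort_config(config)
  rp <- config$rt_params
  ptruth <- truth[truth$participant == participant, ]
  if (nrow(ptruth) == 0) abort("No ground-truth rows for this participant.")
  emo_eff <- setNames(ptruth$rt_effect, ptruth$condition)

  with_seed(derive_seed(config$seed, participant, 5L), {
    n <- nrow(schedule)
    log_rt <- log(rp$base_ms) +
      unname(rp$cue_effect[schedule$cue]) +
      unname(rp$congruency_effect[schedule$congruency]) +
      unname(emo_eff[schedule$condition]) +
      rnorm(n, 0, rp$log_sd)
    rt <- exp(log_rt)
    timeout <- rt > config$timing$timeout_ms
    correct <- rbinom(n, 1, 1 - rp$error_rate) == 1
    tibble(
      participant = participant,
      trial = schedule$trial,
      block = schedule$block,
      condition = schedule$condition,
      cue = schedule$cue,
      congruency = schedule$congruency,
      rt_ms = ifelse(timeout, NA_real_, rt),
      timeout = timeout,
      correct = ifelse(timeout, NA, correct)
    )
  })
}

#' Simulate a complete multimodal session
#'
#' Convenience wrapper producing the schedule, EEG recording, SCR trace
#' and trial table for one participant under a shared configuration and
#' ground truth.
#'
#' @inheritParams simulate_eeg
#' @param modalities Character subset of `c("eeg", "scr", "rt")`; streams
#'   not requested are skipped (useful for cheap reaction-time-only or
#'   conductance-only simulations).
#' @return A list with elements `schedule`, `eeg`, `scr`, `trials`.
#' @export
simulate_session <- function(truth, config, participant = 1L,
                             modalities = c("eeg", "scr", "rt")) {
  sched <- build_schedule(config, participant)
  list(
    schedule = sched,
    eeg = if ("eeg" %in% modalities) simulate_eeg(truth, sched, config, participant) else NULL,
    scr = if ("scr" %in% modalities) simulate_scr(truth, sched, config, participant) else NULL,
    trials = if ("rt" %in% modalities) simulate_rt(truth, sched, config, participant) else NULL
  )
}
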