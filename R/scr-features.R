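# Zero-phase FIR filtering via FFT convolution, forward and reversed.
fir_zerophase <- function(b, x) {
  nb <- length(b)
  pass <- function(v) {
    # pad with edge reflection to tame boundary transients
    pad <- min(nb, length(v))
    vp <- c(rev(v[seq_len(pad)]), v, rev(v[length(v) - seq_len(pad) + 1]))
    # FFT convolution at a power-of-two length
    nfft <- stats::nextn(length(vp) + nb - 1, 2)
    y <- Re(fft(fft(c(vp, numeric(nfft - length(vp)))) *
                  fft(c(b, numeric(nfft - nb))), inverse = TRUE)) / nfft
    y[(nb - 1) / 2 + pad + seq_along(v)]
  }
  rev(pass(rev(pass(x))))
}

#' High-pass filter a skin-conductance trace
#'
#' Zero-phase linear-phase FIR high-pass (window-design), applied forward
#' and backward over the entire series; removes the DC/tonic level while
#' leaving phasic frequencies essentially untouched. The validity mask is
#' propagated unchanged. The default order gives roughly a 0.1 Hz
#' transition width at a 60 Hz sampling rate.
#'
#' @param trace An `scr_trace`.
#' @param cutoff Cutoff frequency in Hz (< rate/2).
#' @param order FIR order (even); default `ceiling(3.3 * rate / 0.1)`
#'   rounded to even, i.e. a Hamming-window design with ~0.1 Hz
#'   transition.
#' @return The filtered `scr_trace`.
#' @export
scr_highpass <- function(trace, cutoff = 0.05, order = NULL) {
  rate <- trace$rate
  if (cutoff >= rate / 2) abort("`cutoff` must be below the Nyquist frequency.")
  if (is.null(order)) {
    order <- ceiling(3.3 * rate / 0.1)
    order <- order + order %% 2
  }
  min_len <- 3 * order + 3
  if (length(trace$conductance) < min_len) {
    abort(sprintf(
      "Series too short for the filter transient: %d samples given, at least %d required (order %d). Supply a smaller `order` or a longer trace.",
      length(trace$conductance), min_len, order))
  }
  # Complement of a unity-DC low-pass: exact zero gain at DC even when the
  # cutoff sits deep inside the first transition band.
  b <- signal::fir1(order, cutoff / (rate / 2), type = "low")
  b <- -as.numeric(b) / sum(b) # unity-DC low-pass, negated
  b[order / 2 + 1] <- b[order / 2 + 1] + 1
  trace$conductance <- fir_zerophase(b, trace$conductance)
  trace
}

#' Score one trial's phasic skin-conductance response
#'
#' Max-change score: the maximum, over the response window from picture
#' onset to 500 ms before the next trial, of the conductance minus the
#' baseline (the mean over the 500 ms fixation period preceding picture
#' onset). Responses that never rise above baseline are floored at zero,
#' the standard magnitude convention that also keeps the later log
#' transform finite. Trials whose windows touch invalid (between-block)
#' samples score `NA`.
#'
#' @param trace A (filtered) `scr_trace`.
#' @param onset_s Picture onset in seconds.
#' @param next_onset_s Next trial's picture onset (or end of the block's
#'   valid span) in seconds.
#' @return A single max-change score, or `NA` if a window is invalid.
#' @export
scr_trial_score <- function(trace, onset_s, next_onset_s) {
  rate <- trace$rate
  n <- length(trace$conductance)
  base_idx <- (floor((onset_s - 0.5) * rate) + 1L):floor(onset_s * rate)
  resp_idx <- (floor(onset_s * rate) + 1L):floor((next_onset_s - 0.5) * rate)
  if (min(base_idx) < 1 || max(resp_idx) > n) return(NA_real_)
  if (any(!trace$valid[base_idx]) || any(!trace$valid[resp_idx])) return(NA_real_)
  baseline <- mean(trace$conductance[base_idx])
  max(0, max(trace$conductance[resp_idx]) - baseline)
}

#' Score every trial of a trace
#'
#' Applies [scr_trial_score()] to each event of the trace.
#'
#' @param trace A (filtered) `scr_trace` carrying trial events.
#' @param participant Participant id attached to the rows.
#' @return A tibble: `participant`, `trial`, `block`, `condition`,
#'   `scr_score`.
#' @export
scr_score_trials <- function(trace, participant = trace$participant) {
  ev <- trace$events
  scores <- vapply(seq_len(nrow(ev)), function(i) {
    scr_trial_score(trace, ev$onset_s[i], ev$next_onset_s[i])
  }, numeric(1))
  tibble(participant = participant, trial = ev$trial, block = ev$block,
         condition = ev$condition, scr_score = scores)
}

#' Aggregate trial-level SCR scores
#'
#' Each raw max-change score `s` is transformed to `log(1 + s)` to reduce
#' skewness, then averaged per cell (condition, or condition by block).
#' Missing trials are excluded and counted; empty cells are `NA` with a
#' warning.
#'
#' @param scores Output of [scr_score_trials()].
#' @param by `"condition"` or `c("condition", "block")`.
#' @return A tibble with grouping columns, `scr_log`, `n_trials`.
#' @export
scr_aggregate <- function(scores, by = "condition") {
  cells <- scores |>
    dplyr::filter(!is.na(.data$scr_score)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant", by)))) |>
    dplyr::summarise(scr_log = mean(log1p(.data$scr_score)),
                     n_trials = dplyr::n(), .groups = "drop")
  full <- scores |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("participant", by))))
  out <- dplyr::left_join(full, cells, by = c("participant", by))
  out$n_trials[is.na(out$n_trials)] <- 0L
  if (any(out$n_trials == 0)) {
    warn("Some SCR cells have no valid trials; their values are NA.")
  }
  out
}
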