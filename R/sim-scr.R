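#' Bateman kernel for phasic skin-conductance responses
#'
#' Difference-of-exponentials impulse response
#' `(exp(-t/decay) - exp(-t/rise))`, normalised to unit peak, the standard
#' shape model for a phasic electrodermal response.
#'
#' @param t_s Time points in seconds (>= 0).
#' @param rise_s,decay_s Rise and decay time constants in seconds; must
#'   differ.
#' @return Kernel values, unit peak.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1 / 60)
#' max(bateman_kernel(t))
bateman_kernel <- function(t_s, rise_s = 0.75, decay_s = 2.0) {
  if (rise_s == decay_s) abort("Bateman kernel is degenerate when rise and decay time constants are equal.")
  g <- exp(-t_s / decay_s) - exp(-t_s / rise_s)
  g[t_s < 0] <- 0
  t_peak <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  peak <- exp(-t_peak / decay_s) - exp(-t_peak / rise_s)
  g / peak
}

#' @rdname simulate_scr
#' @export
new_scr_trace <- function(conductance, rate, events = tibble(),
                          valid = rep(TRUE, length(conductance)),
                          participant = NA_integer_) {
  if (length(valid) != length(conductance)) {
    abort("`valid` mask must match the series length.")
  }
  if (rate <= 0) abort("`rate` must be positive.")
  if (nrow(events) > 0 && is.unsorted(events$onset_s)) {
    abort("Events must be sorted by onset.")
  }
  structure(list(conductance = conductance,
                 time_s = seq_along(conductance) / rate - 1 / rate,
                 rate = rate, events = events, valid = valid,
                 participant = participant),
            class = "scr_trace")
}

#' @export
print.scr_trace <- function(x, ...) {
  cat("<scr_trace> ", length(x$conductance), " samples @ ", x$rate,
      " Hz, ", nrow(x$events), " events, ",
      sum(!x$valid), " masked samples\n", sep = "")
  invisible(x)
}

#' Simulate a skin-conductance trace for one participant
#'
#' Sums, over trials, Bateman-kernel phasic responses whose amplitudes are
#' the planted condition drivers (condition mean plus trait loading,
#' floored at zero) plus trial-level jitter, on top of a slow tonic drift
#' and white measurement noise. Samples falling in the between-block
#' breaks, when the participant's fingers are out of the sensor, are
#' marked invalid in the mask and never interpolated.
#'
#' @inheritParams simulate_eeg
#' @return An `scr_trace`: conductance series (arbitrary conductance
#'   units), sampling rate, trial events (with per-trial scoring windows),
#'   and validity mask.
#' @export
simulate_scr <- function(truth, schedule, config, participant = 1L) {
  validate_cohort_config(config)
  sp <- config$scr_params
  rate <- config$scr_rate
  ptruth <- truth[truth$participant == participant, ]
  if (nrow(ptruth) == 0) abort("No ground-truth rows for this participant.")
  driver <- setNames(ptruth$scr_driver, ptruth$condition)

  with_seed(derive_seed(config$seed, participant, 4L), {
    n_t <- ceiling((max(schedule$block_end_s) + 10) * rate)
    x <- numeric(n_t)
    kern <- bateman_kernel(seq(0, 15, by = 1 / rate), sp$rise_s, sp$decay_s)
    amps <- pmax(0, unname(driver[schedule$condition]) +
                   rnorm(nrow(schedule), 0, sp$driver_trial_sd))
    onset_sample <- floor((schedule$onset_s + sp$latency_s) * rate) + 1L
    for (i in seq_len(nrow(schedule))) {
      idx <- onset_sample[i] + seq_along(kern) - 1L
      keep <- idx <= n_t
      x[idx[keep]] <- x[idx[keep]] + amps[i] * kern[keep]
    }
    if (sp$drift_sd > 0) {
      x <- x + colored_noise(n_t, rate, sp$drift_sd, exponent = 2, alpha_power = 0)
    }
    if (sp$noise_sd > 0) x <- x + rnorm(n_t, 0, sp$noise_sd)

    valid <- rep(TRUE, n_t)
    blocks <- unique(schedule[, c("block", "block_start_s", "block_end_s")])
    for (b in seq_len(nrow(blocks) - 1)) {
      lo <- floor(blocks$block_end_s[b] * rate) + 1L
      hi <- floor(blocks$block_start_s[b + 1] * rate)
      valid[seq(lo, min(hi, n_t))] <- FALSE
    }
    events <- tibble(
      onset_s = schedule$onset_s,
      next_onset_s = schedule$next_onset_s,
      trial = schedule$trial,
      block = schedule$block,
      condition = schedule$condition
    )
    new_scr_trace(x, rate, events, valid, participant)
  })
}
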