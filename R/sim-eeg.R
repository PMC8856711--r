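#' @rdname simulate_eeg
#' @export
new_recording <- function(samples, rate, labels,
                          events = tibble(), participant = NA_integer_) {
  if (!is.matrix(samples)) abort("`samples` must be a channel x time matrix.")
  if (nrow(samples) != length(labels)) abort("One label per channel row is required.")
  if (anyDuplicated(labels)) abort("Channel labels must be unique.")
  if (nrow(events) > 0) {
    if (is.unsorted(events$onset_sample)) abort("Events must be sorted by onset.")
    if (any(events$onset_sample < 1 | events$onset_sample > ncol(samples))) {
      abort("Event onsets must lie within the recorded sample range.")
    }
  }
  structure(list(samples = samples, rate = rate, labels = labels,
                 events = events, participant = participant),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$samples), " channels x ", ncol(x$samples),
      " samples @ ", x$rate, " Hz, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

# Gaussian temporal kernel sampled on epoch-relative indices, normalised so
# that its mean over the component's analysis window (same half-open sample
# convention as feature extraction) equals 1. Returns the sampled kernel for
# relative sample offsets 0 .. support-1.
erp_kernel <- function(peak_ms, sd_ms, window_ms, rate) {
  support <- seq(0L, floor((peak_ms + 5 * sd_ms) / 1000 * rate))
  t_ms <- support / rate * 1000
  g <- exp(-((t_ms - peak_ms)^2) / (2 * sd_ms^2))
  win_idx <- window_sample_offsets(window_ms, rate)
  gain <- mean(g[match(win_idx, support)])
  g / gain
}

# Half-open window [a, b) in ms -> integer sample offsets relative to onset,
# floor(t * rate) convention used throughout the package.
window_sample_offsets <- function(window_ms, rate) {
  seq(floor(window_ms[1] / 1000 * rate), floor(window_ms[2] / 1000 * rate) - 1L)
}

# Average-reference-consistent spatial patterns: unit mean weight over the
# channels entering the component's analysis, zero mean over the montage.
erp_spatial_pattern <- function(labels, analysis_weights) {
  w <- setNames(numeric(length(labels)), labels)
  w[names(analysis_weights)] <- analysis_weights
  extra <- setdiff(labels, names(analysis_weights))
  if (length(extra) > 0) w[extra] <- -sum(analysis_weights) / length(extra)
  unname(w[labels])
}

# 1/f + alpha-band background noise via spectral shaping. Generated at the
# next power-of-two length (fast FFT) and truncated.
colored_noise <- function(n, rate, rms, exponent = 1, alpha_power = 1) {
  if (rms <= 0) return(numeric(n))
  n2 <- stats::nextn(n, 2)
  m <- n2 / 2
  f <- seq(0, rate / 2, length.out = m + 1)
  psd <- 1 / pmax(f, 0.5)^exponent +
    alpha_power * exp(-((f - 10)^2) / (2 * 1.5^2))
  psd[1] <- 0
  shape <- sqrt(psd)
  # Draw the positive-frequency spectrum directly (one inverse FFT).
  re <- rnorm(m + 1); im <- rnorm(m + 1)
  spec <- complex(real = re * shape, imaginary = im * shape)
  spec[1] <- 0
  spec[m + 1] <- complex(real = re[m + 1] * shape[m + 1], imaginary = 0)
  full <- c(spec, Conj(spec[m:2]))
  x <- Re(fft(full, inverse = TRUE)) / n2
  x <- x[seq_len(n)]
  x * rms / sd(x)
}

#' Simulate an event-related EEG recording for one participant
#'
#' Generates a continuous multichannel recording containing, for every
#' trial, a P300-like bump (Gaussian in time, peaking near 300 ms, spatial
#' weights largest at Fz/Cz) and an LPP-like bump (peaking near 650 ms,
#' largest at Cz/Pz), riding on 1/f-plus-alpha background noise. Bump
#' amplitudes are the planted per-condition values from the ground truth
#' (condition mean plus trait loading) plus independent trial-level
#' jitter. Optionally, ocular-like high-amplitude transients are injected
#' on the frontal channel at a configured rate so that downstream artifact
#' rejection has something to find.
#'
#' Spatial patterns are zero-mean across the montage (the forward model is
#' expressed in average-reference space), so average re-referencing leaves
#' the event-related signal untouched, and temporal kernels are normalised
#' to unit mean over the component's analysis window, so planted
#' amplitudes are in measured-feature microvolts.
#'
#' @param truth A [sample_traits()] table.
#' @param schedule A [build_schedule()] table for the same participant.
#' @param config A [cohort_config()].
#' @param participant Participant index.
#' @return An `eeg_recording`: channel x time matrix in microvolts, rate,
#'   labels, and picture-onset events.
#' @export
simulate_eeg <- function(truth, schedule, config, participant = 1L) {
  validate_cohort_config(config)
  labels <- config$channel_labels
  rate <- config$eeg_rate
  cp <- config$component_params
  np <- config$noise_params
  ptruth <- truth[truth$participant == participant, ]
  if (nrow(ptruth) == 0) abort("No ground-truth rows for this participant.")
  amp_p300 <- setNames(ptruth$p300_amp_uv, ptruth$condition)
  amp_lpp <- setNames(ptruth$lpp_amp_uv, ptruth$condition)

  with_seed(derive_seed(config$seed, participant, 3L), {
    # The EEG recording is paused during between-block breaks: its
    # timeline compresses each break to a short `eeg_gap_s` (default 4 s)
    # while the schedule and SCR keep real time. Epochs never span breaks,
    # so downstream quantities are unaffected.
    eeg_gap_s <- config$timing$eeg_gap_s %||% 4
    gap_delta <- max(0, config$timing$block_gap_s - eeg_gap_s)
    eeg_onset_s <- schedule$onset_s - (schedule$block - 1L) * gap_delta
    n_t <- ceiling((max(eeg_onset_s) + 3) * rate)
    n_ch <- length(labels)
    X <- matrix(0, n_ch, n_t)
    if (np$eeg_rms_uv > 0) {
      for (ch in seq_len(n_ch)) {
        X[ch, ] <- colored_noise(n_t, rate, np$eeg_rms_uv,
                                 np$one_over_f_exponent, np$alpha_power)
      }
    }

    k_p300 <- erp_kernel(cp$p300_peak_ms, cp$p300_sd_ms, c(250, 350), rate)
    k_lpp <- erp_kernel(cp$lpp_peak_ms, cp$lpp_sd_ms, c(500, 800), rate)
    w_p300 <- erp_spatial_pattern(labels, c(Fz = 1.1, Cz = 1.0, Pz = 0.9))
    w_lpp <- erp_spatial_pattern(labels, c(Fz = 0.5, Cz = 1.05, Pz = 0.95))

    onset_sample <- floor(eeg_onset_s * rate) + 1L
    jit_p300 <- rnorm(nrow(schedule), 0, cp$amp_trial_sd_uv)
    jit_lpp <- rnorm(nrow(schedule), 0, cp$amp_trial_sd_uv)
    art_hit <- if (np$artifact_rate > 0) {
      rbinom(nrow(schedule), 1, np$artifact_rate) == 1
    } else rep(FALSE, nrow(schedule))
    # Blink-like transient: 300 ms half-sine on the frontal channel.
    art_kern <- sin(pi * seq(0, floor(0.3 * rate)) / floor(0.3 * rate))
    fz <- match("Fz", labels)

    for (i in seq_len(nrow(schedule))) {
      cond <- schedule$condition[i]
      s0 <- onset_sample[i]
      idx <- s0 + seq_along(k_p300) - 1L
      X[, idx] <- X[, idx] + outer(w_p300, k_p300) * (amp_p300[[cond]] + jit_p300[i])
      idx <- s0 + seq_along(k_lpp) - 1L
      X[, idx] <- X[, idx] + outer(w_lpp, k_lpp) * (amp_lpp[[cond]] + jit_lpp[i])
      if (art_hit[i]) {
        idx <- s0 + floor(0.15 * rate) + seq_along(art_kern) - 1L
        X[fz, idx] <- X[fz, idx] + np$artifact_amp_uv * art_kern
      }
    }

    events <- tibble(
      onset_sample = onset_sample,
      trial = schedule$trial,
      block = schedule$block,
      condition = schedule$condition
    )
    new_recording(X, rate, labels, events, participant)
  })
}
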