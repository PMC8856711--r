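#' Configuration for a synthetic multimodal cohort
#'
#' Builds and validates the full parameter set for the synthetic-cohort
#' generator: session structure (10 blocks of trials, each of the five
#' emotion conditions appearing in exactly two blocks, one per session
#' half), trial timing, event-related EEG component parameters, phasic
#' skin-conductance parameters, reaction-time model parameters, the latent
#' responder-trait model, and noise levels.
#'
#' The defaults emulate the study conditions the pipeline is designed for:
#' an affective picture shown for 80 ms at trial onset, a fixation period
#' drawn uniformly from 900--1300 ms, a 100 ms cue followed by 400 ms of
#' fixation, and a flanker target with a 1700 ms response deadline. EEG is
#' sampled at 128 Hz (configurable, must be at least 100 Hz so the ERP
#' analysis windows contain enough samples) and skin conductance at 60 Hz.
#'
#' Component amplitudes are specified in *measured-feature units*: the
#' temporal kernel of each event-related bump is normalised so that its
#' mean over the component's analysis window equals 1, and the spatial
#' pattern is average-reference-consistent (zero mean across the montage)
#' with unit mean weight over the channels entering that component's
#' analysis. A planted amplitude of `a` microvolts therefore reproduces,
#' up to filtering and noise, a channel-averaged window mean of `a`
#' microvolts downstream, which is what makes parameter-recovery testing
#' direct.
#'
#' @param n_participants Number of participants to simulate.
#' @param eeg_rate EEG sampling rate in Hz (>= 100).
#' @param scr_rate Skin-conductance sampling rate in Hz.
#' @param channel_labels EEG montage (10--20 names); must contain
#'   `"Fz"`, `"Cz"`, `"Pz"`.
#' @param trials_per_block Trials per block; must be divisible by 6 so the
#'   three cue types and two congruency levels balance within block.
#' @param timing Named list: `picture_ms`, `fixation_min_ms`,
#'   `fixation_max_ms`, `cue_ms`, `post_cue_fix_ms`, `timeout_ms`,
#'   `post_target_s` (nominal interval from target onset to the next
#'   picture), `block_gap_s` (between-block break), and
#'   `fixation_anchor` (`"offset"` to measure the randomized fixation from
#'   picture offset, `"onset"` to measure it from picture onset).
#' @param component_params Named list with per-condition `p300_amp_uv` and
#'   `lpp_amp_uv` (named by condition), bump shape parameters
#'   (`p300_peak_ms`, `p300_sd_ms`, `lpp_peak_ms`, `lpp_sd_ms`) and
#'   `amp_trial_sd_uv` (trial-to-trial amplitude jitter).
#' @param scr_params Named list: Bateman kernel time constants `rise_s`
#'   and `decay_s`, per-condition `driver` amplitudes (arbitrary
#'   conductance units), `latency_s`, `noise_sd`, `drift_sd`.
#' @param rt_params Named list: `base_ms`, `cue_effect` (named log-RT
#'   offsets for spatial/center/none), `congruency_effect` (named offsets),
#'   `log_sd` (residual log-RT SD), `error_rate`.
#' @param trait_params Named list: `trait_sd`, loadings `load_erp_uv`,
#'   `load_scr`, `load_rt` of the per-emotion latent trait onto ERP
#'   amplitude, SCR driver, and signed RT effect, and `rt_shift` (named
#'   per-emotion mean signed RT effect; 0 gives an even
#'   facilitated/impeded split in expectation).
#' @param noise_params Named list: `eeg_rms_uv` (background EEG RMS),
#'   `alpha_power` (relative 10 Hz alpha peak power), `one_over_f_exponent`,
#'   `artifact_rate` (fraction of trials receiving a high-amplitude
#'   ocular-like transient), `artifact_amp_uv`.
#' @param seed Integer seed; the same configuration and seed yield
#'   identical cohorts.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 2, seed = 1)
#' cfg$timing$picture_ms
cohort_config <- function(n_participants = 26,
                          eeg_rate = 128,
                          scr_rate = 60,
                          channel_labels = c("Fz", "Cz", "Pz", "F3", "F4", "Oz"),
                          trials_per_block = 24,
                          timing = list(),
                          component_params = list(),
                          scr_params = list(),
                          rt_params = list(),
                          trait_params = list(),
                          noise_params = list(),
                          seed = 1L) {
  timing <- utils::modifyList(list(
    picture_ms = 80,
    fixation_min_ms = 900,
    fixation_max_ms = 1300,
    cue_ms = 100,
    post_cue_fix_ms = 400,
    timeout_ms = 1700,
    post_target_s = 1.2,
    block_gap_s = 120,
    fixation_anchor = "offset"
  ), timing)

  component_params <- utils::modifyList(list(
    p300_amp_uv = c(neutral = 4, positive = 4.5, erotic = 6,
                    mutilation = 4.5, horror = 6),
    lpp_amp_uv = c(neutral = 3, positive = 3.3, erotic = 5.5,
                   mutilation = 3.8, horror = 5),
    p300_peak_ms = 300, p300_sd_ms = 40,
    lpp_peak_ms = 650, lpp_sd_ms = 120,
    amp_trial_sd_uv = 2
  ), component_params)

  scr_params <- utils::modifyList(list(
    rise_s = 0.75, decay_s = 2.0,
    driver = c(neutral = 0.10, positive = 0.10, erotic = 0.12,
               mutilation = 0.13, horror = 0.20),
    latency_s = 1.0,
    driver_trial_sd = 0.05,
    noise_sd = 0.01,
    drift_sd = 0.05
  ), scr_params)

  rt_params <- utils::modifyList(list(
    base_ms = 560,
    cue_effect = c(spatial = -0.08, center = -0.04, none = 0),
    congruency_effect = c(congruent = 0, incongruent = 0.05),
    log_sd = 0.12,
    error_rate = 0.02
  ), rt_params)

  trait_params <- utils::modifyList(list(
    trait_sd = 1,
    load_erp_uv = 1.5,
    load_scr = 0.05,
    load_rt = 0.08,
    rt_shift = c(positive = 0, erotic = 0, mutilation = 0, horror = 0)
  ), trait_params)

  noise_params <- utils::modifyList(list(
    eeg_rms_uv = 6,
    alpha_power = 1,
    one_over_f_exponent = 1,
    artifact_rate = 0.05,
    artifact_amp_uv = 150
  ), noise_params)

  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    eeg_rate = eeg_rate,
    scr_rate = scr_rate,
    channel_labels = channel_labels,
    conditions = EMOTION_CONDITIONS,
    trials_per_block = as.integer(trials_per_block),
    n_blocks = 2L * length(EMOTION_CONDITIONS),
    timing = timing,
    component_params = component_params,
    scr_params = scr_params,
    rt_params = rt_params,
    trait_params = trait_params,
    noise_params = noise_params,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) abort("`n_participants` must be >= 1.")
  if (cfg$eeg_rate < 100) {
    abort("`eeg_rate` must be >= 100 Hz so the 250-350 ms and 500-800 ms windows contain at least 10 samples.")
  }
  if (cfg$scr_rate <= 0) abort("`scr_rate` must be positive.")
  if (!all(ANALYSIS_CHANNELS %in% cfg$channel_labels)) {
    abort("`channel_labels` must include the analysis channels Fz, Cz and Pz.")
  }
  if (anyDuplicated(cfg$channel_labels)) abort("`channel_labels` must be unique.")
  if (length(cfg$conditions) < 5) {
    abort("The block plan needs the five emotion conditions; fewer make the balance constraints impossible.")
  }
  if (cfg$trials_per_block < 6 || cfg$trials_per_block %% 6 != 0) {
    abort("`trials_per_block` must be a positive multiple of 6 (3 cue types x 2 congruency levels).")
  }
  tm <- cfg$timing
  pos <- c(tm$picture_ms, tm$fixation_min_ms, tm$fixation_max_ms, tm$cue_ms,
           tm$post_cue_fix_ms, tm$timeout_ms, tm$post_target_s, tm$block_gap_s)
  if (any(!is.finite(pos)) || any(pos <= 0)) abort("All timing values must be strictly positive.")
  if (tm$fixation_min_ms > tm$fixation_max_ms) {
    abort("`fixation_min_ms` must not exceed `fixation_max_ms`.")
  }
  if (!tm$fixation_anchor %in% c("offset", "onset")) {
    abort("`fixation_anchor` must be \"offset\" or \"onset\".")
  }
  for (fld in c("p300_amp_uv", "lpp_amp_uv")) {
    if (!all(cfg$conditions %in% names(cfg$component_params[[fld]]))) {
      abort(paste0("`component_params$", fld, "` must name every condition."))
    }
  }
  if (!all(cfg$conditions %in% names(cfg$scr_params$driver))) {
    abort("`scr_params$driver` must name every condition.")
  }
  if (cfg$scr_params$rise_s == cfg$scr_params$decay_s) {
    abort("Bateman kernel is degenerate when rise and decay time constants are equal.")
  }
  tp <- cfg$trait_params
  if (!is.finite(tp$trait_sd) || tp$trait_sd < 0) abort("`trait_sd` must be finite and >= 0.")
  if (!all(EMOTIONS_NONNEUTRAL %in% names(tp$rt_shift))) {
    abort("`trait_params$rt_shift` must name every non-neutral emotion.")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  participants:", x$n_participants,
      "| EEG", x$eeg_rate, "Hz x", length(x$channel_labels), "channels",
      "| SCR", x$scr_rate, "Hz\n")
  cat("  session:", x$n_blocks, "blocks x", x$trials_per_block, "trials,",
      length(x$conditions), "conditions, seed", x$seed, "\n")
  invisible(x)
}

# Deterministic per-participant, per-stream seed derivation (kept < 2^31).
derive_seed <- function(seed, participant, stream = 0L) {
  (as.double(seed) * 7919 + as.double(participant) * 104729 +
     as.double(stream) * 15485863) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
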