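options(emoattn.quiet = TRUE)

# Small, fast cohort configuration for tests that exercise the full
# signal path; overrides merge into the package defaults.
tiny_config <- function(n_participants = 1, seed = 1, ...) {
  base <- list(
    n_participants = n_participants,
    trials_per_block = 6,
    timing = list(block_gap_s = 5),
    seed = seed
  )
  args <- utils::modifyList(base, list(...))
  do.call(cohort_config, args)
}

# Noise-free deterministic variant: no background EEG, no jitter, no
# artifacts, no trait spread.
clean_config <- function(n_participants = 1, seed = 1, ...) {
  base <- list(
    n_participants = n_participants, seed = seed,
    component_params = list(amp_trial_sd_uv = 0),
    noise_params = list(eeg_rms_uv = 0, artifact_rate = 0),
    scr_params = list(driver_trial_sd = 0, noise_sd = 0, drift_sd = 0),
    rt_params = list(log_sd = 0, error_rate = 0),
    trait_params = list(trait_sd = 0)
  )
  do.call(tiny_config, utils::modifyList(base, list(...)))
}

# Build an epoch_set directly from an array (trial x channel x time),
# bypassing the signal path, for feature-level unit tests.
make_epochs <- function(data, rate = 1000,
                        channels = paste0("ch", seq_len(dim(data)[2])),
                        condition = rep("neutral", dim(data)[1]),
                        block = rep(1L, dim(data)[1]),
                        rejected = rep(FALSE, dim(data)[1])) {
  off <- seq(floor(-0.1 * rate), floor(1.0 * rate) - 1L)
  stopifnot(dim(data)[3] == length(off))
  structure(list(
    data = data,
    time_ms = off / rate * 1000,
    rate = rate,
    channels = channels,
    trials = tibble::tibble(
      onset_sample = NA_integer_,
      trial = seq_len(dim(data)[1]),
      block = block, condition = condition
    ),
    mask = tibble::tibble(
      trial = seq_len(dim(data)[1]),
      rejected = rejected,
      reason = ifelse(rejected, "amplitude", NA_character_)
    )
  ), class = "epoch_set")
}

# Synthetic block-level feature tables for classifier tests: one latent
# score per participant drives both the features and the label.
make_feature_tables <- function(n_participants, separation = 2,
                                n_features = 2, scr_signal = 0,
                                seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c("facilitated", "impeded"), length.out = n_participants)
    mu <- ifelse(lab == "impeded", separation, 0)
    erp <- purrr::map_dfr(seq_len(n_participants), function(p) {
      tibble::tibble(
        participant = p, block = 1:2,
        e_p300 = rnorm(2, mu[p], 1),
        e_lpp = if (n_features >= 2) rnorm(2, mu[p], 1) else rnorm(2, 0, 1)
      )
    })
    scr <- purrr::map_dfr(seq_len(n_participants), function(p) {
      tibble::tibble(participant = p, block = 1:2,
                     e_scr = rnorm(2, scr_signal * mu[p], 1))
    })
    labels <- tibble::tibble(participant = seq_len(n_participants),
                             emotion = "horror", label = lab)
    list(erp = erp, scr = scr, labels = labels)
  })
}
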