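# --- EEG forward model -----------------------------------------------------

test_that("noise-free P300 window mean matches the analytic bump value", {
  cfg <- clean_config(seed = 4)
  truth <- suppressWarnings(sample_traits(cfg))
  sched <- build_schedule(cfg, 1)
  rec <- simulate_eeg(truth, sched, cfg, 1)
  epochs <- eeg_baseline_correct(eeg_epoch(rec))

  # Analytic oracle, written out from the generator's definition: Gaussian
  # bump, unit window mean by construction, times the Fz spatial weight
  # (1.1) and the planted amplitude; the LPP bump's tail adds its own
  # analytically computed contribution to the window.
  rate <- cfg$eeg_rate
  off <- seq(floor(0.25 * rate), floor(0.35 * rate) - 1)
  t_ms <- off / rate * 1000
  g_p300 <- exp(-((t_ms - 300)^2) / (2 * 40^2))
  g_p300 <- g_p300 / mean(g_p300) # unit window mean
  g_lpp <- exp(-((t_ms - 650)^2) / (2 * 120^2))
  lpp_off <- seq(floor(0.5 * rate), floor(0.8 * rate) - 1)
  lpp_t <- lpp_off / rate * 1000
  g_lpp <- g_lpp / mean(exp(-((lpp_t - 650)^2) / (2 * 120^2)))

  amp_p <- cfg$component_params$p300_amp_uv[["horror"]]
  amp_l <- cfg$component_params$lpp_amp_uv[["horror"]]
  expected <- 1.1 * amp_p * mean(g_p300) + 0.5 * amp_l * mean(g_lpp)

  meas <- component_amplitude(epochs, c(250, 350), "Fz")
  hor <- mean(meas[epochs$trials$condition == "horror"])
  expect_lt(abs(hor - expected) / expected, 0.05)
})

test_that("zero amplitudes and zero noise give an all-zero recording", {
  cfg <- clean_config(
    seed = 9,
    component_params = list(
      p300_amp_uv = c(neutral = 0, positive = 0, erotic = 0, mutilation = 0, horror = 0),
      lpp_amp_uv = c(neutral = 0, positive = 0, erotic = 0, mutilation = 0, horror = 0),
      amp_trial_sd_uv = 0))
  truth <- suppressWarnings(sample_traits(cfg))
  rec <- simulate_eeg(truth, build_schedule(cfg, 1), cfg, 1)
  expect_true(all(rec$samples == 0))
})

test_that("artifact injection produces a binomially plausible rejection count", {
  cfg <- cohort_config(n_participants = 1, seed = 21,
                       timing = list(block_gap_s = 5),
                       noise_params = list(artifact_rate = 0.1))
  truth <- sample_traits(cfg)
  rec <- simulate_eeg(truth, build_schedule(cfg, 1), cfg, 1)
  epochs <- eeg_reject_artifacts(eeg_baseline_correct(eeg_epoch(eeg_rereference(eeg_bandpass(rec)))))
  n_rej <- sum(epochs$mask$reason == "amplitude", na.rm = TRUE)
  # 240 trials at rate 0.1: 99.9% binomial band
  expect_gte(n_rej, qbinom(0.0005, 240, 0.1))
  expect_lte(n_rej, qbinom(0.9995, 240, 0.1))
})

test_that("EEG simulation is bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 31)
  truth <- sample_traits(cfg)
  sched <- build_schedule(cfg, 1)
  expect_identical(simulate_eeg(truth, sched, cfg, 1),
                   simulate_eeg(truth, sched, cfg, 1))
})

# --- SCR forward model -----------------------------------------------------

test_that("a single planted pulse is recovered at the kernel peak", {
  # one unit-driver response on a flat trace; the max-change score should
  # equal the (unit) kernel peak up to sampling of the maximum
  rate <- 60
  t <- seq(0, 60, by = 1 / rate)
  x <- numeric(length(t))
  onset <- 10
  idx <- which(t >= onset + 1) # generator's 1 s latency convention
  x[idx] <- bateman_kernel(t[idx] - (onset + 1))
  trace <- new_scr_trace(x, rate,
                         events = tibble::tibble(onset_s = onset,
                                                 next_onset_s = 30,
                                                 trial = 1L, block = 1L,
                                                 condition = "horror"))
  sc <- scr_trial_score(trace, onset, 30)
  # dense-grid oracle for the kernel maximum
  dense <- max(bateman_kernel(seq(0, 15, by = 1e-4)))
  expect_lt(abs(sc - dense) / dense, 0.02)
})

test_that("zero drivers and zero noise give a flat trace and zero scores", {
  cfg <- clean_config(
    seed = 13,
    scr_params = list(driver = c(neutral = 0, positive = 0, erotic = 0,
                                 mutilation = 0, horror = 0)))
  truth <- suppressWarnings(sample_traits(cfg))
  trace <- simulate_scr(truth, build_schedule(cfg, 1), cfg, 1)
  expect_true(all(trace$conductance == 0))
  sc <- scr_score_trials(trace)
  expect_true(all(sc$scr_score[!is.na(sc$scr_score)] == 0))
})

test_that("between-block samples are masked invalid", {
  cfg <- tiny_config(seed = 14)
  truth <- sample_traits(cfg)
  sched <- build_schedule(cfg, 1)
  trace <- simulate_scr(truth, sched, cfg, 1)
  expect_gt(sum(!trace$valid), 0)
  # a sample in the middle of the first break is invalid
  mid <- floor((sched$block_end_s[sched$block == 1][1] + 2.5) * cfg$scr_rate)
  expect_false(trace$valid[mid])
  # a sample in the middle of the first block is valid
  mid1 <- floor(mean(c(sched$block_start_s[1], sched$block_end_s[1])) * cfg$scr_rate)
  expect_true(trace$valid[mid1])
})

test_that("stronger horror drivers raise mean horror scores across a cohort", {
  cfg <- tiny_config(
    n_participants = 100, seed = 15,
    trait_params = list(load_scr = 0, load_rt = 0.08, load_erp_uv = 1.5))
  truth <- sample_traits(cfg)
  diffs <- vapply(seq_len(cfg$n_participants), function(p) {
    sched <- build_schedule(cfg, p)
    sc <- scr_score_trials(scr_highpass(simulate_scr(truth, sched, cfg, p)))
    agg <- scr_aggregate(sc, by = "condition")
    agg$scr_log[agg$condition == "horror"] - agg$scr_log[agg$condition == "neutral"]
  }, numeric(1))
  # one-sided Monte-Carlo check: planted horror > neutral
  tt <- one_sample_t(diffs)
  expect_gt(mean(diffs), 0)
  expect_lt(tt$p / 2, 0.01)
})

# --- RT model ---------------------------------------------------------------

test_that("noise-free RT reproduces the planted additive structure exactly", {
  cfg <- clean_config(seed = 16)
  truth <- suppressWarnings(sample_traits(cfg))
  sched <- build_schedule(cfg, 1)
  rt <- simulate_rt(truth, sched, cfg, 1)
  expected <- exp(log(cfg$rt_params$base_ms) +
                    cfg$rt_params$cue_effect[rt$cue] +
                    cfg$rt_params$congruency_effect[rt$congruency])
  expect_equal(rt$rt_ms, unname(expected), tolerance = 1e-12)
})

test_that("planted cue and congruency orderings hold per participant", {
  cfg <- tiny_config(n_participants = 8, seed = 17,
                     trials_per_block = 24,
                     rt_params = list(log_sd = 0.02))
  truth <- sample_traits(cfg)
  for (p in seq_len(cfg$n_participants)) {
    rt <- simulate_rt(truth, build_schedule(cfg, p), cfg, p)
    m <- tapply(log(rt$rt_ms), rt$cue, mean, na.rm = TRUE)
    expect_lt(m[["spatial"]], m[["center"]])
    expect_lt(m[["center"]], m[["none"]])
    mc <- tapply(log(rt$rt_ms), rt$congruency, mean, na.rm = TRUE)
    expect_lt(mc[["congruent"]], mc[["incongruent"]])
  }
})

test_that("a slow baseline produces timeouts that are excluded downstream", {
  cfg <- tiny_config(seed = 18, rt_params = list(base_ms = 1500, log_sd = 0.3))
  truth <- sample_traits(cfg)
  rt <- simulate_rt(truth, build_schedule(cfg, 1), cfg, 1)
  expect_gt(sum(rt$timeout), 0)
  expect_true(all(is.na(rt$rt_ms[rt$timeout])))
  means <- rt_condition_means(rt, by = "condition")
  expect_equal(sum(means$n_timeouts), sum(rt$timeout))
  expect_equal(sum(means$n_trials), sum(!rt$timeout))
})
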