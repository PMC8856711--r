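#' Build the trial schedule for one participant
#'
#' Lays out the full session: the ten blocks are ordered so that each
#' emotion condition appears once in the first half and once in the second
#' half, with no condition occupying two consecutive blocks (in particular
#' blocks 5 and 6 differ). Within each block the three cue types and the
#' two congruency levels are fully crossed and balanced, in randomized
#' order. Absolute onsets are accumulated from the timing constants: the
#' picture at trial onset, the randomized fixation period, the cue, the
#' post-cue fixation, then the target; the next trial starts a fixed
#' nominal interval after target onset, and blocks are separated by the
#' configured break.
#'
#' @param config A [cohort_config()].
#' @param participant Participant index (1-based); together with
#'   `config$seed` it determines the schedule deterministically.
#' @return A tibble with one row per trial: `trial`, `block`,
#'   `block_trial`, `condition`, `cue`, `congruency`, `onset_s` (picture
#'   onset), `fixation_s`, `cue_onset_s`, `target_onset_s`, `next_onset_s`
#'   (next picture onset, or end of the block's valid recording span for
#'   the last trial of a block), `block_start_s`, `block_end_s`.
#' @export
#' @examples
#' sched <- build_schedule(cohort_config(n_participants = 1, seed = 7), 1)
#' table(sched$condition)
build_schedule <- function(config, participant = 1L) {
  validate_cohort_config(config)
  with_seed(derive_seed(config$seed, participant, 1L), {
    k <- length(config$conditions)
    # Block order: permute conditions per half until the half boundary is
    # clean (no condition in consecutive blocks).
    repeat {
      first <- sample(config$conditions)
      second <- sample(config$conditions)
      if (tail(first, 1) != second[1]) break
    }
    block_conditions <- c(first, second)

    tm <- config$timing
    npb <- config$trials_per_block
    cell <- expand.grid(cue = CUE_TYPES, congruency = CONGRUENCY_TYPES,
                        stringsAsFactors = FALSE)
    reps <- npb / nrow(cell)

    rows <- vector("list", config$n_blocks)
    cursor <- 2 # lead-in so the first epoch and SCR baseline have data
    trial_id <- 0L
    for (b in seq_len(config$n_blocks)) {
      ord <- sample.int(npb)
      cues <- rep(cell$cue, reps)[ord]
      congr <- rep(cell$congruency, reps)[ord]
      fix_s <- runif(npb, tm$fixation_min_ms, tm$fixation_max_ms) / 1000
      block_start <- cursor
      onset <- numeric(npb); cue_on <- numeric(npb); target_on <- numeric(npb)
      for (i in seq_len(npb)) {
        onset[i] <- cursor
        anchor <- if (tm$fixation_anchor == "offset") tm$picture_ms / 1000 else 0
        cue_on[i] <- onset[i] + anchor + fix_s[i]
        target_on[i] <- cue_on[i] + (tm$cue_ms + tm$post_cue_fix_ms) / 1000
        cursor <- target_on[i] + tm$post_target_s
      }
      block_end <- cursor
      rows[[b]] <- tibble(
        trial = trial_id + seq_len(npb),
        block = b,
        block_trial = seq_len(npb),
        condition = block_conditions[b],
        cue = cues,
        congruency = congr,
        onset_s = onset,
        fixation_s = fix_s,
        cue_onset_s = cue_on,
        target_onset_s = target_on,
        next_onset_s = c(onset[-1], block_end),
        block_start_s = block_start,
        block_end_s = block_end
      )
      trial_id <- trial_id + npb
      cursor <- cursor + tm$block_gap_s
    }
    out <- dplyr::bind_rows(rows)
    out$half <- ifelse(out$block <= config$n_blocks / 2, 1L, 2L)
    out
  })
}
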