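#' Default ERP component windows
#'
#' P300 is the mean voltage over \[250, 350) ms and the late positive
#' potential (LPP) over \[500, 800) ms after picture onset; both windows
#' use the package-wide half-open convention.
#'
#' @return A named list of two-element ms vectors.
#' @export
erp_windows <- function() list(p300 = c(250, 350), lpp = c(500, 800))

#' Mean voltage in a time window, per trial
#'
#' Arithmetic mean of the samples in a half-open window of the epoch time
#' axis at one channel. Masked epochs yield `NA`.
#'
#' @param epochs An `epoch_set`.
#' @param window Two-element numeric, window in ms (half-open).
#' @param channel Channel label.
#' @return A numeric vector, one value per trial (microvolts).
#' @export
component_amplitude <- function(epochs, window, channel) {
  ch <- match(channel, epochs$channels)
  if (is.na(ch)) abort(paste0("Unknown channel: ", channel))
  off <- window_sample_offsets(window, epochs$rate)
  idx <- match(off, round(epochs$time_ms / 1000 * epochs$rate))
  if (anyNA(idx)) abort("Window does not lie inside the epoch time axis.")
  vals <- rowMeans(epochs$data[, ch, idx, drop = FALSE], dims = 1)
  vals[epochs$mask$rejected] <- NA_real_
  as.numeric(vals)
}

#' Per-trial ERP component amplitudes at the analysis channels
#'
#' Computes the P300 and LPP window means for every retained trial at each
#' requested channel, in long format.
#'
#' @param epochs An `epoch_set`.
#' @param channels Channels to measure (default Fz, Cz, Pz).
#' @param windows Component windows, see [erp_windows()].
#' @param participant Participant id attached to the rows.
#' @return A tibble: `participant`, `trial`, `block`, `condition`,
#'   `channel`, `p300_uv`, `lpp_uv`, `rejected`.
#' @export
erp_trial_features <- function(epochs, channels = ANALYSIS_CHANNELS,
                               windows = erp_windows(),
                               participant = NA_integer_) {
  purrr::map_dfr(channels, function(ch) {
    tibble(
      participant = participant,
      trial = epochs$trials$trial,
      block = epochs$trials$block,
      condition = epochs$trials$condition,
      channel = ch,
      p300_uv = component_amplitude(epochs, windows$p300, ch),
      lpp_uv = component_amplitude(epochs, windows$lpp, ch),
      rejected = epochs$mask$rejected
    )
  })
}

#' Aggregate per-trial ERP features to condition or condition-by-block cells
#'
#' Unweighted mean over retained trials in each cell; condition-level
#' aggregation therefore pools trials (trial-weighted) rather than
#' averaging block means, while block-level cells exist separately for
#' classification. Empty cells are kept with `NA` and a warning, never a
#' silent zero.
#'
#' @param trial_features Output of [erp_trial_features()] (any number of
#'   participants bound together).
#' @param by `"condition"` or `c("condition", "block")`.
#' @param block_equal_weight If `TRUE`, condition means weight blocks
#'   equally (mean of block means) instead of pooling trials.
#' @return A tibble with the grouping columns, `p300_uv`, `lpp_uv`, and
#'   the retained-trial count `n_trials`.
#' @export
erp_aggregate <- function(trial_features, by = "condition",
                          block_equal_weight = FALSE) {
  keep <- dplyr::filter(trial_features, !.data$rejected)
  if (block_equal_weight && identical(by, "condition")) {
    cells <- keep |>
      dplyr::group_by(.data$participant, .data$channel, .data$condition, .data$block) |>
      dplyr::summarise(p300_uv = mean(.data$p300_uv),
                       lpp_uv = mean(.data$lpp_uv),
                       n_trials = dplyr::n(), .groups = "drop") |>
      dplyr::group_by(.data$participant, .data$channel, .data$condition) |>
      dplyr::summarise(p300_uv = mean(.data$p300_uv),
                       lpp_uv = mean(.data$lpp_uv),
                       n_trials = sum(.data$n_trials), .groups = "drop")
  } else {
    cells <- keep |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c("participant", "channel", by)))) |>
      dplyr::summarise(p300_uv = mean(.data$p300_uv),
                       lpp_uv = mean(.data$lpp_uv),
                       n_trials = dplyr::n(), .groups = "drop")
  }
  full <- trial_features |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("participant", "channel", by))))
  out <- dplyr::left_join(full, cells,
                          by = c("participant", "channel", by))
  out$n_trials[is.na(out$n_trials)] <- 0L
  if (any(out$n_trials == 0)) {
    warn("Some cells have no retained trials; their values are NA.")
  }
  out
}

#' Channel-averaged component amplitudes for classification
#'
#' Averages P300 over Fz, Cz and Pz and LPP over Cz and Pz (the channel
#' sets that showed no channel main effect in the analyses these features
#' feed), per participant, condition, and any further grouping columns
#' present (e.g. block).
#'
#' @param features Aggregated ERP features with a `channel` column.
#' @return A tibble with `p300_avg` and `lpp_avg` per remaining cell.
#' @export
erp_channel_average <- function(features) {
  need <- ANALYSIS_CHANNELS
  if (!all(need %in% unique(features$channel))) {
    abort("Channel averaging requires Fz, Cz and Pz to be present.")
  }
  grp <- setdiff(names(features),
                 c("channel", "p300_uv", "lpp_uv", "n_trials"))
  p300 <- features |>
    dplyr::filter(.data$channel %in% c("Fz", "Cz", "Pz")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(p300_avg = mean(.data$p300_uv), .groups = "drop")
  lpp <- features |>
    dplyr::filter(.data$channel %in% c("Cz", "Pz")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(lpp_avg = mean(.data$lpp_uv), .groups = "drop")
  dplyr::left_join(p300, lpp, by = grp)
}
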