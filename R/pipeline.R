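#' Extract single-session features from raw signals
#'
#' Runs the fixed preprocessing and feature-extraction chain for one
#' simulated (or loaded) session: EEG band-pass, average re-reference,
#' epoching, baseline correction, artifact screening, ERP window means at
#' Fz/Cz/Pz; SCR high-pass and per-trial max-change scoring; and the raw
#' trial table passthrough. Each output row carries the session half
#' (blocks 1-5 vs 6-10), the unit of "block-averaged" values downstream,
#' since every condition occupies exactly one block per half.
#'
#' @param session A [simulate_session()] list (elements may be `NULL`).
#' @param config The generating [cohort_config()].
#' @param participant Participant id.
#' @return A list with `erp_trials`, `scr_scores`, `trials`.
#' @export
extract_session_features <- function(session, config, participant) {
  half_of <- function(block) ifelse(block <= config$n_blocks / 2, 1L, 2L)
  erp <- scrs <- NULL
  if (!is.null(session$eeg)) {
    epochs <- eeg_preprocess(session$eeg)
    erp <- erp_trial_features(epochs, participant = participant)
    erp$half <- half_of(erp$block)
  }
  if (!is.null(session$scr)) {
    filtered <- scr_highpass(session$scr)
    scrs <- scr_score_trials(filtered, participant = participant)
    scrs$half <- half_of(scrs$block)
  }
  trials <- session$trials
  if (!is.null(trials)) trials$half <- half_of(trials$block)
  list(erp_trials = erp, scr_scores = scrs, trials = trials)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end driver: simulate every participant's multimodal session,
#' preprocess and extract features, compute E difference scores for every
#' modality, assign facilitated/impeded labels from the sign of E_RT,
#' build the statistical table (one-sample t tests per emotion with
#' Bonferroni correction over the four emotion comparisons, plus
#' repeated-measures ANOVAs), and run unimodal and multimodal
#' cross-validated classification per emotion. Sessions are processed one
#' at a time and raw signals are discarded after feature extraction, so
#' memory stays flat in cohort size.
#'
#' @param config A [cohort_config()].
#' @param classify_emotions Emotions to classify (default all four).
#' @param cv_folds,cv_seed,cv_cost Cross-validation settings.
#' @param stages Character subset of
#'   `c("features", "stats", "classify")`; `"features"` runs simulation +
#'   signal processing. Supplying `precomputed` (a previous run's value)
#'   with `stages` lacking `"features"` reuses its feature tables and
#'   skips all signal processing.
#' @param precomputed A previous `emoattn_run` to reuse features from.
#' @param out_dir Optional directory; when given, the statistical table,
#'   classification report, E scores, labels and a provenance JSON are
#'   written there.
#' @param quiet Suppress per-stage log messages.
#' @return An object of class `emoattn_run`: list with `truth`,
#'   `features` (trial-level tables), `escores`, `labels`, `stats`,
#'   `classification` (summary tibble), `reports` (named list of
#'   `classifier_report`s), `comparisons`, `provenance`.
#' @export
run_pipeline <- function(config,
                         classify_emotions = EMOTIONS_NONNEUTRAL,
                         cv_folds = 10, cv_seed = NULL, cv_cost = 1,
                         stages = c("features", "stats", "classify"),
                         precomputed = NULL,
                         out_dir = NULL,
                         quiet = TRUE) {
  old_opt <- options(emoattn.quiet = quiet)
  on.exit(options(old_opt))
  cv_seed <- cv_seed %||% config$seed

  if ("features" %in% stages || is.null(precomputed)) {
    truth <- sample_traits(config)
    erp_trials <- vector("list", config$n_participants)
    scr_scores <- vector("list", config$n_participants)
    trials <- vector("list", config$n_participants)
    for (p in seq_len(config$n_participants)) {
      session <- simulate_session(truth, config, p)
      fx <- extract_session_features(session, config, p)
      erp_trials[[p]] <- fx$erp_trials
      scr_scores[[p]] <- fx$scr_scores
      trials[[p]] <- fx$trials
      if (!quiet) inform(sprintf("participant %d/%d processed", p, config$n_participants))
    }
    features <- list(
      erp_trials = dplyr::bind_rows(erp_trials),
      scr_scores = dplyr::bind_rows(scr_scores),
      trials = dplyr::bind_rows(trials)
    )
  } else {
    truth <- precomputed$truth
    features <- precomputed$features
  }

  # ---- E scores -----------------------------------------------------------
  rt_cond <- rt_condition_means(features$trials, by = "condition")
  e_rt <- escore(rt_cond, "log_rt", "RT")
  labels <- assign_groups(e_rt)

  erp_cond <- erp_aggregate(features$erp_trials, by = "condition")
  e_p300 <- escore(erp_cond, "p300_uv", "P300")
  e_lpp <- escore(erp_cond, "lpp_uv", "LPP")

  scr_cond <- scr_aggregate(features$scr_scores, by = "condition")
  e_scr <- escore(scr_cond, "scr_log", "SCR")

  escores <- dplyr::bind_rows(
    e_rt,
    e_scr,
    dplyr::select(e_p300, dplyr::everything()),
    dplyr::select(e_lpp, dplyr::everything())
  )

  # Half-wise ("block-averaged") scores for classification.
  erp_half <- erp_aggregate(features$erp_trials, by = c("condition", "half"))
  erp_half_avg <- erp_channel_average(erp_half)
  e_p300_half <- escore(erp_half_avg, "p300_avg", "P300")
  e_lpp_half <- escore(erp_half_avg, "lpp_avg", "LPP")
  scr_half <- scr_aggregate(features$scr_scores, by = c("condition", "half"))
  e_scr_half <- escore(scr_half, "scr_log", "SCR")

  out <- list(truth = truth, features = features, escores = escores,
              labels = labels,
              block_escores = dplyr::bind_rows(e_p300_half, e_lpp_half,
                                               e_scr_half))

  # ---- Statistics ---------------------------------------------------------
  if ("stats" %in% stages) {
    if (!"channel" %in% names(escores)) escores$channel <- NA_character_
    one_sample_table <- escores |>
      dplyr::group_by(.data$modality, .data$channel) |>
      dplyr::group_modify(function(g, key) {
        res <- purrr::map_dfr(EMOTIONS_NONNEUTRAL, function(emo) {
          v <- g$value[g$emotion == emo]
          r <- one_sample_t(v[!is.na(v)])
          r$emotion <- emo
          r
        })
        res$p_corrected <- bonferroni(res$p, 4)
        res
      }) |>
      dplyr::ungroup()

    anova_rt_cell <- rt_condition_means(
      features$trials, by = c("condition", "cue", "congruency"))
    rt_anova <- rm_anova(anova_rt_cell, "log_rt",
                         c("condition", "cue", "congruency"))
    e_anova <- escores |>
      dplyr::filter(.data$modality %in% c("RT", "SCR")) |>
      dplyr::group_by(.data$modality) |>
      dplyr::group_modify(function(g, key) {
        rm_anova(g, "value", "emotion")
      }) |>
      dplyr::ungroup()
    erp_anova <- purrr::map_dfr(c("P300", "LPP"), function(m) {
      g <- escores[escores$modality == m & !is.na(escores$channel), ]
      res <- rm_anova(g, "value", c("channel", "emotion"))
      res$modality <- m
      res
    })
    out$stats <- list(one_sample = one_sample_table,
                      rt_anova = rt_anova,
                      escore_anova = e_anova,
                      erp_anova = erp_anova)
  }

  # ---- Classification -----------------------------------------------------
  if ("classify" %in% stages) {
    reports <- list()
    comparisons <- list()
    for (emo in classify_emotions) {
      erp_f <- dplyr::inner_join(
        e_p300_half |> dplyr::filter(.data$emotion == emo) |>
          dplyr::select("participant", block = "half", e_p300 = "value"),
        e_lpp_half |> dplyr::filter(.data$emotion == emo) |>
          dplyr::select("participant", block = "half", e_lpp = "value"),
        by = c("participant", "block"))
      scr_f <- e_scr_half |> dplyr::filter(.data$emotion == emo) |>
        dplyr::select("participant", block = "half", e_scr = "value")
      lab <- labels[labels$emotion == emo, ]
      uni <- crossval_classify(
        build_features(erp_f, NULL, lab, emo, "unimodal"),
        k = cv_folds, seed = cv_seed, cost = cv_cost)
      multi <- crossval_classify(
        build_features(erp_f, scr_f, lab, emo, "multimodal"),
        k = cv_folds, seed = cv_seed, cost = cv_cost)
      reports[[paste0(emo, "_unimodal")]] <- uni
      reports[[paste0(emo, "_multimodal")]] <- multi
      comparisons[[emo]] <- compare_modalities(uni, multi)
    }
    out$reports <- reports
    out$comparisons <- comparisons
    out$classification <- purrr::map_dfr(reports, glance)
  }

  out$provenance <- list(
    package_version = as.character(utils::packageVersion("emoattn")),
    seed = config$seed,
    cv_seed = cv_seed,
    n_participants = config$n_participants,
    stage_counts = list(
      erp_trial_rows = nrow(features$erp_trials %||% tibble()),
      erp_rejected = if (!is.null(features$erp_trials))
        sum(features$erp_trials$rejected) / max(1, length(unique(features$erp_trials$channel)))
      else NA,
      scr_missing = if (!is.null(features$scr_scores))
        sum(is.na(features$scr_scores$scr_score)) else NA,
      rt_timeouts = if (!is.null(features$trials))
        sum(features$trials$timeout) else NA
    ),
    config = unclass(config)
  )
  class(out) <- "emoattn_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out$escores, file.path(out_dir, "escores.tsv"), progress = FALSE)
    readr::write_tsv(out$labels, file.path(out_dir, "group_labels.tsv"), progress = FALSE)
    if (!is.null(features$erp_trials)) {
      readr::write_tsv(
        erp_aggregate(features$erp_trials, by = c("condition", "block")),
        file.path(out_dir, "erp_features.tsv"), progress = FALSE)
    }
    if (!is.null(features$scr_scores)) {
      readr::write_tsv(features$scr_scores,
                       file.path(out_dir, "scr_trial_scores.tsv"), progress = FALSE)
      readr::write_tsv(
        scr_aggregate(features$scr_scores, by = c("condition", "block")),
        file.path(out_dir, "scr_features.tsv"), progress = FALSE)
    }
    if (!is.null(out$stats)) {
      readr::write_tsv(out$stats$one_sample,
                       file.path(out_dir, "statistical_table.tsv"), progress = FALSE)
      readr::write_tsv(dplyr::bind_rows(out$stats$rt_anova, out$stats$escore_anova,
                                        out$stats$erp_anova),
                       file.path(out_dir, "anova_table.tsv"), progress = FALSE)
    }
    if (!is.null(out$classification)) {
      readr::write_tsv(out$classification,
                       file.path(out_dir, "classification_report.tsv"), progress = FALSE)
      jsonlite::write_json(out$classification,
                           file.path(out_dir, "classification_report.json"),
                           digits = NA)
    }
    jsonlite::write_json(out$provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

#' @export
print.emoattn_run <- function(x, ...) {
  cat("<emoattn_run> ", x$provenance$n_participants, " participants, seed ",
      x$provenance$seed, "\n", sep = "")
  if (!is.null(x$classification)) {
    print(x$classification[, c("emotion", "modality", "mean_accuracy", "mean_auc")])
  }
  invisible(x)
}

#' @export
glance.emoattn_run <- function(x, ...) {
  tibble(
    n_participants = x$provenance$n_participants,
    seed = x$provenance$seed,
    n_escores = nrow(x$escores),
    n_labels = sum(!is.na(x$labels$label))
  )
}
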