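#' Assemble per-block classification features from a pipeline run
#'
#' Pulls the block-averaged (session-half) E scores for one emotion out
#' of a [run_pipeline()] result and builds the unimodal or multimodal
#' [build_features()] matrix.
#'
#' @param run An `emoattn_run`.
#' @param emotion Emotion condition to classify.
#' @param modality `"unimodal"` or `"multimodal"`.
#' @param labels Optional replacement label table (defaults to the run's
#'   sign-rule labels); used e.g. for permutation nulls.
#' @return A `feature_matrix`.
#' @export
run_feature_matrix <- function(run, emotion,
                               modality = c("multimodal", "unimodal"),
                               labels = NULL) {
  modality <- match.arg(modality)
  be <- run$block_escores[run$block_escores$emotion == emotion, ]
  wide <- be |>
    dplyr::select("participant", block = "half", "modality", "value") |>
    tidyr::pivot_wider(names_from = "modality", values_from = "value")
  erp <- dplyr::select(wide, "participant", "block",
                       e_p300 = "P300", e_lpp = "LPP")
  scr <- dplyr::select(wide, "participant", "block", e_scr = "SCR")
  lab <- labels %||% run$labels[run$labels$emotion == emotion, ]
  build_features(erp, if (modality == "multimodal") scr else NULL,
                 lab, emotion, modality)
}

#' Replicate-cohort calibration of the multimodal classifier
#'
#' Simulates `n_replicates` independent cohorts with the configured
#' planted trait-linked effects, runs the full pipeline (signals,
#' features, E scores, sign-rule labels) on each, classifies the chosen
#' emotion with the grouped stratified 10-fold linear-margin classifier,
#' and collects the per-replicate mean fold accuracy, mean AUC, and the
#' fold-level t test against the 50% chance level.
#'
#' @param n_participants Cohort size per replicate.
#' @param n_replicates Number of replicate cohorts.
#' @param base_seed Seed offset; replicate r uses seed `base_seed + r`.
#' @param emotion Emotion condition classified.
#' @param modality Feature set.
#' @param folds Cross-validation folds.
#' @param config_args Extra arguments forwarded to [cohort_config()].
#' @return A list: `replicates` (tibble with `seed`, `mean_accuracy`,
#'   `mean_auc`, `chance_p`), `grand_mean_accuracy`, `grand_mean_auc`,
#'   `rejection_rate` (share of replicates whose chance test rejects at
#'   0.05).
#' @export
classification_calibration <- function(n_participants = 26,
                                       n_replicates = 20,
                                       base_seed = 1,
                                       emotion = "horror",
                                       modality = "multimodal",
                                       folds = 10,
                                       config_args = list()) {
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- do.call(cohort_config, utils::modifyList(
      list(n_participants = n_participants, seed = base_seed + r),
      config_args))
    run <- suppressWarnings(
      run_pipeline(cfg, classify_emotions = character(0),
                   stages = "features"))
    fm <- run_feature_matrix(run, emotion, modality)
    rep <- crossval_classify(fm, k = folds, seed = base_seed + r)
    tibble(seed = base_seed + r,
           mean_accuracy = attr(rep, "mean_accuracy"),
           mean_auc = attr(rep, "mean_auc"),
           chance_p = attr(rep, "chance_p"))
  })
  list(replicates = reps,
       grand_mean_accuracy = mean(reps$mean_accuracy),
       grand_mean_auc = mean(reps$mean_auc),
       rejection_rate = mean(reps$chance_p < 0.05))
}

#' Permutation null for the cross-validated AUC
#'
#' Permutes the facilitated/impeded labels at the participant level and
#' reruns the cross-validated classifier, returning one mean AUC per
#' permutation. Under permutation the grand mean should sit at chance.
#'
#' @param run An `emoattn_run`.
#' @param emotion Emotion condition.
#' @param modality Feature set.
#' @param n_permutations Number of label permutations.
#' @param base_seed Seed offset.
#' @return Numeric vector of mean AUCs, one per permutation.
#' @export
permutation_null_auc <- function(run, emotion, modality = "multimodal",
                                 n_permutations = 50, base_seed = 1) {
  lab0 <- run$labels[run$labels$emotion == emotion, ]
  lab0 <- lab0[!is.na(lab0$label) & lab0$label != "undefined", ]
  vapply(seq_len(n_permutations), function(i) {
    lab <- lab0
    lab$label <- with_seed(base_seed + i, sample(lab0$label))
    fm <- run_feature_matrix(run, emotion, modality, labels = lab)
    attr(crossval_classify(fm, seed = base_seed + i), "mean_auc")
  }, numeric(1))
}
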