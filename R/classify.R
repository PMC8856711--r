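#' Assemble the classification feature matrix
#'
#' One row per participant and block: channel-averaged `e_p300` and
#' `e_lpp` (and `e_scr` when multimodal), labelled with the participant's
#' facilitated/impeded group in the given emotion. Participants with an
#' undefined label, and (for multimodal features) participants absent
#' from the SCR set, are dropped and the drops logged; rows with missing
#' feature cells are dropped likewise.
#'
#' @param erp Block-level channel-averaged E scores: columns
#'   `participant`, `block`, `e_p300`, `e_lpp` (one emotion at a time).
#' @param scr Block-level E_SCR scores (`participant`, `block`, `e_scr`),
#'   or `NULL` for unimodal features.
#' @param labels Group labels from [assign_groups()], already filtered to
#'   the emotion of interest (columns `participant`, `label`).
#' @param emotion Emotion tag carried into the result.
#' @param modality `"unimodal"` (P300 + LPP) or `"multimodal"`
#'   (P300 + LPP + SCR).
#' @return A tibble of class `feature_matrix` with attributes `emotion`
#'   and `modality`.
#' @export
build_features <- function(erp, scr = NULL, labels, emotion,
                           modality = c("unimodal", "multimodal")) {
  modality <- match.arg(modality)
  lab <- labels[!is.na(labels$label) & labels$label != "undefined", ]
  dropped_undef <- setdiff(labels$participant, lab$participant)
  out <- dplyr::inner_join(erp, lab[, c("participant", "label")],
                           by = "participant")
  if (modality == "multimodal") {
    if (is.null(scr)) abort("Multimodal features require SCR scores.")
    before <- unique(out$participant)
    out <- dplyr::inner_join(out, scr, by = c("participant", "block"))
    dropped_scr <- setdiff(before, unique(out$participant))
    if (length(dropped_scr) > 0 && !isTRUE(getOption("emoattn.quiet"))) {
      inform(paste("Participants without SCR features dropped:",
                   paste(dropped_scr, collapse = ", ")))
    }
  }
  feat_cols <- c("e_p300", "e_lpp", if (modality == "multimodal") "e_scr")
  keep <- stats::complete.cases(out[, feat_cols])
  if (any(!keep) && !isTRUE(getOption("emoattn.quiet"))) {
    inform(sprintf("%d rows with missing feature cells dropped.", sum(!keep)))
  }
  out <- out[keep, c("participant", "block", feat_cols, "label")]
  if (length(dropped_undef) > 0 && !isTRUE(getOption("emoattn.quiet"))) {
    inform(paste("Participants with undefined labels excluded:",
                 paste(dropped_undef, collapse = ", ")))
  }
  n_class <- table(unique(out[, c("participant", "label")])$label)
  if (length(n_class) < 2 || any(n_class < 4)) {
    abort("Insufficient data: need at least 4 participants in each of the facilitated and impeded classes.")
  }
  out$label <- factor(out$label, levels = c("facilitated", "impeded"))
  structure(out, class = c("feature_matrix", class(tibble())),
            emotion = emotion, modality = modality)
}

# Stratified, participant-grouped fold assignment: participants of each
# class are shuffled and dealt onto a cyclic fold counter that continues
# across classes, so each class spreads as evenly as possible and every
# fold is non-empty whenever there are at least k participants.
make_folds <- function(participants, labels, k, seed) {
  with_seed(seed, {
    fold <- setNames(integer(length(participants)), participants)
    cursor <- 0L
    for (cl in levels(labels)) {
      ps <- sample(participants[labels == cl])
      fold[as.character(ps)] <- (cursor + seq_along(ps) - 1L) %% k + 1L
      cursor <- cursor + length(ps)
    }
    fold
  })
}

#' Cross-validated maximum-margin classification
#'
#' Linear-kernel support-vector classification (fixed regularisation
#' constant) with k-fold cross-validation. Folds are stratified by label
#' and grouped by participant: both block rows of a participant always
#' fall in the same fold, so no participant contributes to both the
#' training and test side of any fold. Within each training fold the
#' features are standardised by the *training* statistics only, and the
#' same location/scale is applied to the test rows. Per-fold accuracy and
#' AUC (from the decision scores) are summarised by their mean and
#' standard error across folds, and the fold accuracies are compared with
#' the 50% chance level by a one-sample t test.
#'
#' Test folds that happen to contain a single class (possible when the
#' group split is unbalanced) have no defined AUC and are excluded from
#' the AUC mean; a training fold with a single class triggers a re-draw
#' of the folds with an incremented seed (error after 10 attempts).
#'
#' @param features A [build_features()] matrix.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold draw.
#' @param cost Regularisation constant of the margin.
#' @return An object of class `classifier_report`: tibble of per-fold
#'   `accuracy` (percent) and `auc`, with summary attributes
#'   (`mean_accuracy`, `se_accuracy`, `mean_auc`, `se_auc`,
#'   `chance_t`, `chance_p`, `emotion`, `modality`, `seed`, `folds`).
#' @export
crossval_classify <- function(features, k = 10, seed = 1, cost = 1) {
  feat_cols <- intersect(c("e_p300", "e_lpp", "e_scr"), names(features))
  parts <- unique(features[, c("participant", "label")])
  if (k > nrow(parts)) abort("More folds than participants.")
  if (min(table(parts$label)) < 1) abort("Both classes must be present.")

  fold_map <- NULL
  for (attempt in 0:9) {
    cand <- make_folds(parts$participant, parts$label, k, seed + attempt)
    row_fold <- cand[as.character(features$participant)]
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(features$label[row_fold != f])) == 2
    }, logical(1)))
    if (ok) { fold_map <- cand; break }
  }
  if (is.null(fold_map)) {
    abort("Could not draw folds whose training sides contain both classes (10 attempts).")
  }
  row_fold <- fold_map[as.character(features$participant)]

  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- features[row_fold != f, ]
    te <- features[row_fold == f, ]
    mu <- vapply(tr[feat_cols], mean, numeric(1))
    sg <- vapply(tr[feat_cols], sd, numeric(1))
    sg[sg == 0] <- 1
    Xtr <- scale(as.matrix(tr[feat_cols]), mu, sg)
    Xte <- scale(as.matrix(te[feat_cols]), mu, sg)
    fit <- e1071::svm(Xtr, tr$label, kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")[, 1]
    # Orient the score so that larger means "impeded".
    if (colnames(attr(pred, "decision.values")) == "facilitated/impeded") dv <- -dv
    auc <- if (length(unique(te$label)) == 2) {
      as.numeric(pROC::auc(pROC::roc(
        response = te$label, predictor = dv,
        levels = c("facilitated", "impeded"), direction = "<",
        quiet = TRUE)))
    } else NA_real_
    tibble(fold = f, n_test = nrow(te),
           accuracy = 100 * mean(pred == te$label), auc = auc)
  })

  acc <- per_fold$accuracy
  auc <- per_fold$auc[!is.na(per_fold$auc)]
  ct <- if (sd(acc) > 0) t.test(acc, mu = 50) else NULL
  structure(per_fold,
            class = c("classifier_report", class(tibble())),
            emotion = attr(features, "emotion"),
            modality = attr(features, "modality"),
            seed = seed, folds = k,
            mean_accuracy = mean(acc),
            se_accuracy = sd(acc) / sqrt(length(acc)),
            mean_auc = mean(auc),
            se_auc = sd(auc) / sqrt(length(auc)),
            chance_t = if (is.null(ct)) Inf else unname(ct$statistic),
            chance_p = if (is.null(ct)) 0 else ct$p.value,
            fold_map = fold_map)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s / %s: accuracy %.1f%% (SE %.2f), AUC %.3f (SE %.3f), t vs 50%% = %.2f (p = %.3g)\n",
              attr(x, "modality") %||% "?", attr(x, "emotion") %||% "?",
              attr(x, "mean_accuracy"), attr(x, "se_accuracy"),
              attr(x, "mean_auc"), attr(x, "se_auc"),
              attr(x, "chance_t"), attr(x, "chance_p")))
  invisible(x)
}

#' @export
glance.classifier_report <- function(x, ...) {
  tibble(
    emotion = attr(x, "emotion"), modality = attr(x, "modality"),
    mean_accuracy = attr(x, "mean_accuracy"),
    se_accuracy = attr(x, "se_accuracy"),
    mean_auc = attr(x, "mean_auc"), se_auc = attr(x, "se_auc"),
    chance_t = attr(x, "chance_t"), chance_p = attr(x, "chance_p"),
    folds = attr(x, "folds"), seed = attr(x, "seed")
  )
}

#' @export
tidy.classifier_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "classifier_report")
  out
}

#' Compare unimodal and multimodal classification
#'
#' Paired per-fold differences (multimodal minus unimodal) of accuracy
#' and AUC for reports computed on the same emotion with the same fold
#' structure; reports only the observed differences and their sign
#' summary.
#'
#' @param unimodal,multimodal `classifier_report`s sharing emotion, seed
#'   and fold assignment.
#' @return A list with the per-fold difference tibble and summary means.
#' @export
compare_modalities <- function(unimodal, multimodal) {
  if (!identical(attr(unimodal, "emotion"), attr(multimodal, "emotion"))) {
    abort("Reports compare different emotions.")
  }
  fm_u <- attr(unimodal, "fold_map"); fm_m <- attr(multimodal, "fold_map")
  shared <- intersect(names(fm_u), names(fm_m))
  if (!identical(fm_u[shared], fm_m[shared]) ||
      attr(unimodal, "folds") != attr(multimodal, "folds")) {
    abort("Fold structures do not match; rerun both with the same seed and folds.")
  }
  d <- dplyr::inner_join(tidy(unimodal), tidy(multimodal),
                         by = "fold", suffix = c("_uni", "_multi"))
  diff <- tibble(
    fold = d$fold,
    d_accuracy = d$accuracy_multi - d$accuracy_uni,
    d_auc = d$auc_multi - d$auc_uni
  )
  list(
    per_fold = diff,
    mean_d_accuracy = mean(diff$d_accuracy),
    mean_d_auc = mean(diff$d_auc, na.rm = TRUE),
    sign_summary = c(
      accuracy_up = sum(diff$d_accuracy > 0),
      accuracy_down = sum(diff$d_accuracy < 0),
      auc_up = sum(diff$d_auc > 0, na.rm = TRUE),
      auc_down = sum(diff$d_auc < 0, na.rm = TRUE)
    )
  )
}
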