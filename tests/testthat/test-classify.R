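test_that("feature assembly does the bookkeeping", {
  f <- make_feature_tables(26)
  fm <- build_features(f$erp, NULL, f$labels, "horror", "unimodal")
  expect_equal(nrow(fm), 52)
  expect_equal(setdiff(names(fm), c("participant", "block", "label")),
               c("e_p300", "e_lpp"))

  # undefined labels excluded
  lab2 <- f$labels; lab2$label[3] <- "undefined"
  fm2 <- build_features(f$erp, NULL, lab2, "horror", "unimodal")
  expect_false(3 %in% fm2$participant)

  # multimodal: participant missing from the SCR set is dropped
  scr2 <- f$scr[f$scr$participant != 5, ]
  fm3 <- build_features(f$erp, scr2, f$labels, "horror", "multimodal")
  expect_false(5 %in% fm3$participant)
  expect_equal(nrow(fm3), 50)

  # fewer than 4 participants per class is insufficient
  small <- make_feature_tables(6)
  expect_error(build_features(small$erp, NULL, small$labels, "horror", "unimodal"),
               "at least 4")
})

test_that("perfectly separated classes classify perfectly", {
  f <- make_feature_tables(20, separation = 50)
  fm <- build_features(f$erp, NULL, f$labels, "horror", "unimodal")
  rep <- crossval_classify(fm, k = 10, seed = 1)
  expect_equal(attr(rep, "mean_accuracy"), 100)
  expect_equal(attr(rep, "mean_auc"), 1)
})

test_that("folds are grouped by participant and stratified by label", {
  f <- make_feature_tables(26)
  fm <- build_features(f$erp, NULL, f$labels, "horror", "unimodal")
  rep <- crossval_classify(fm, k = 10, seed = 2)
  fold_map <- attr(rep, "fold_map")
  # both rows of each participant share a fold (fold is per participant)
  expect_equal(length(fold_map), 26)
  expect_true(all(fold_map %in% 1:10))
  # stratification: each class spread across folds as evenly as possible
  lab <- unique(fm[, c("participant", "label")])
  for (cl in levels(lab$label)) {
    counts <- table(factor(fold_map[as.character(lab$participant[lab$label == cl])],
                           levels = 1:10))
    expect_lte(max(counts) - min(counts), 1)
  }
})

test_that("cross-validation is deterministic given a seed", {
  f <- make_feature_tables(20, separation = 1)
  fm <- build_features(f$erp, f$scr, f$labels, "horror", "multimodal")
  a <- crossval_classify(fm, seed = 3)
  b <- crossval_classify(fm, seed = 3)
  expect_identical(tidy(a), tidy(b))
  expect_identical(attr(a, "fold_map"), attr(b, "fold_map"))
  c <- crossval_classify(fm, seed = 4)
  expect_false(identical(attr(a, "fold_map"), attr(c, "fold_map")))
})

test_that("standardisation uses training-fold statistics only", {
  # dual-route check: refit every fold with an independent loop that
  # standardises by training statistics; per-fold accuracies must match
  f <- make_feature_tables(20, separation = 1.2)
  fm <- build_features(f$erp, NULL, f$labels, "horror", "unimodal")
  rep <- crossval_classify(fm, k = 5, seed = 5)
  fold_map <- attr(rep, "fold_map")
  row_fold <- fold_map[as.character(fm$participant)]
  feat <- c("e_p300", "e_lpp")
  for (fl in 1:5) {
    tr <- fm[row_fold != fl, ]; te <- fm[row_fold == fl, ]
    mu <- colMeans(tr[feat]); sg <- sapply(tr[feat], sd)
    fit <- e1071::svm(scale(as.matrix(tr[feat]), mu, sg), tr$label,
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(fit, scale(as.matrix(te[feat]), mu, sg))
    acc <- 100 * mean(pred == te$label)
    expect_equal(tidy(rep)$accuracy[fl], acc)
  }
})

test_that("label permutation drives AUC to chance", {
  f <- make_feature_tables(26, separation = 2, seed = 9)
  aucs <- purrr::map_dbl(1:50, function(s) {
    perm <- withr::with_seed(1000 + s,
                             sample(f$labels$label))
    lab <- f$labels; lab$label <- perm
    fm <- build_features(f$erp, NULL, lab, "horror", "unimodal")
    attr(crossval_classify(fm, k = 10, seed = s), "mean_auc")
  })
  expect_gte(mean(aucs), 0.40)
  expect_lte(mean(aucs), 0.60)
})

test_that("AUC tracks the Gaussian two-class closed form", {
  # single informative feature, standardized class separation 2:
  # population AUC = Phi(2 / sqrt(2))
  aucs <- purrr::map_dbl(1:8, function(s) {
    f <- make_feature_tables(40, separation = 2, n_features = 1, seed = s)
    fm <- build_features(f$erp, NULL, f$labels, "horror", "unimodal")
    attr(crossval_classify(fm, k = 10, seed = s), "mean_auc")
  })
  expect_lt(abs(mean(aucs) - pnorm(2 / sqrt(2))), 0.08)
})

test_that("modality comparison reports paired fold differences", {
  f <- make_feature_tables(20, separation = 1)
  fm_u <- build_features(f$erp, NULL, f$labels, "horror", "unimodal")
  fm_m <- build_features(f$erp, f$scr, f$labels, "horror", "multimodal")
  uni <- crossval_classify(fm_u, seed = 6)
  multi <- crossval_classify(fm_m, seed = 6)
  cmp <- compare_modalities(uni, multi)
  expect_equal(nrow(cmp$per_fold), 10)

  # identical feature matrices give identically zero differences
  cmp0 <- compare_modalities(uni, crossval_classify(fm_u, seed = 6))
  expect_true(all(cmp0$per_fold$d_accuracy == 0))
  expect_true(all(cmp0$per_fold$d_auc == 0, na.rm = TRUE))

  # mismatched folds are refused
  expect_error(compare_modalities(uni, crossval_classify(fm_m, seed = 7)),
               "Fold structures")
})

test_that("a pure-noise SCR column barely moves the AUC", {
  d <- purrr::map_dbl(1:20, function(s) {
    f <- make_feature_tables(24, separation = 1.5, scr_signal = 0, seed = 100 + s)
    uni <- crossval_classify(
      build_features(f$erp, NULL, f$labels, "horror", "unimodal"), seed = s)
    multi <- crossval_classify(
      build_features(f$erp, f$scr, f$labels, "horror", "multimodal"), seed = s)
    compare_modalities(uni, multi)$mean_d_auc
  })
  expect_lt(abs(mean(d)), 0.1)
})

test_that("an informative SCR column usually helps the multimodal model", {
  wins <- purrr::map_lgl(1:20, function(s) {
    f <- make_feature_tables(24, separation = 0.8, scr_signal = 1.5,
                             seed = 200 + s)
    uni <- crossval_classify(
      build_features(f$erp, NULL, f$labels, "horror", "unimodal"), seed = s)
    multi <- crossval_classify(
      build_features(f$erp, f$scr, f$labels, "horror", "multimodal"), seed = s)
    compare_modalities(uni, multi)$mean_d_auc >= 0
  })
  expect_gte(mean(wins), 0.8)
})
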