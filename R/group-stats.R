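new_stat_result <- function(...) {
  out <- tibble(...)
  class(out) <- c("stat_result", class(out))
  out
}

#' Effect-size conversions
#'
#' The algebraic identities used throughout the statistical reporting:
#' Cohen's `d = t / sqrt(n)` for one-sample and paired t tests (equal to
#' `mean / sd` of the tested values), the signed-rank effect size
#' `r = Z / sqrt(n)`, and partial eta squared
#' `F * df1 / (F * df1 + df2)` (algebraically identical to
#' `SS_effect / (SS_effect + SS_error)`).
#'
#' @param t,z,f Test statistics.
#' @param n Sample size entering the test.
#' @param df1,df2 Uncorrected numerator and denominator degrees of
#'   freedom.
#' @return A numeric effect size.
#' @export
#' @examples
#' cohens_d_from_t(2.675, 31)
#' r_from_z(2.803, 10)
#' partial_eta_sq(4.955, 3, 90)
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' @rdname cohens_d_from_t
#' @export
r_from_z <- function(z, n) z / sqrt(n)

#' @rdname cohens_d_from_t
#' @export
partial_eta_sq <- function(f, df1, df2) (f * df1) / (f * df1 + df2)

#' One-sample t test with Cohen's d
#'
#' Standard two-sided one-sample t test of `values` against `null`, with
#' `d = t / sqrt(n) = mean / sd`. Zero variance is an error, not a zero
#' p value.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param null Null-hypothesis mean.
#' @return A one-row `stat_result` tibble.
#' @export
one_sample_t <- function(values, null = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort("Need at least two values.")
  if (sd(values) == 0) abort("Zero variance: the t statistic is undefined.")
  ht <- t.test(values, mu = null)
  new_stat_result(
    test = "one-sample t", statistic = unname(ht$statistic),
    df1 = unname(ht$parameter), df2 = NA_real_,
    p = ht$p.value, effect = cohens_d_from_t(unname(ht$statistic), n),
    effect_type = "d", n = n
  )
}

#' Paired t test with Cohen's d
#'
#' One-sample t test on the pairwise differences `a - b`;
#' `d = mean(diff) / sd(diff) = t / sqrt(n)`.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return A one-row `stat_result` tibble.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("Paired vectors must have equal length.")
  out <- one_sample_t(a - b, 0)
  out$test <- "paired t"
  out
}

#' Wilcoxon signed-rank test with effect size r
#'
#' Normal approximation with tie-corrected variance; zero differences are
#' dropped before ranking. By default no continuity correction is applied
#' (the convention of the common commercial implementations whose printed
#' Z values this reproduces); set `correct = TRUE` for the corrected
#' version. The effect size is `r = Z / sqrt(n)` with `n` the number of
#' non-zero differences entering the test. The signed Z carries the
#' direction of the median difference.
#'
#' @param values Numeric vector (differences, or values tested against
#'   `null`).
#' @param null Null location.
#' @param correct Apply the continuity correction.
#' @return A one-row `stat_result` tibble with `statistic` = Z.
#' @export
wilcoxon_signed_rank <- function(values, null = 0, correct = FALSE) {
  d <- values[!is.na(values)] - null
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("All differences are zero; the signed-rank test is undefined.")
  if (n < 5) warn("Fewer than 5 non-zero differences; the normal approximation is poor.")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  cc <- if (correct) 0.5 * sign(w_pos - mu) else 0
  z <- (w_pos - mu - cc) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  new_stat_result(
    test = "wilcoxon signed-rank", statistic = z,
    df1 = NA_real_, df2 = NA_real_, p = min(1, p),
    effect = r_from_z(z, n), effect_type = "r", n = n
  )
}

#' Friedman rank test
#'
#' Rank-based test for a condition effect on a complete
#' subject-by-condition matrix; chi-squared statistic with `k - 1`
#' degrees of freedom.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows,
#'   conditions in columns; no missing cells.
#' @return A one-row `stat_result` tibble.
#' @export
friedman_rank_test <- function(ratings) {
  m <- as.matrix(ratings)
  if (nrow(m) < 2 || ncol(m) < 2) abort("Need at least 2 subjects and 2 conditions.")
  if (anyNA(m)) abort("Missing cells are not allowed in the Friedman test.")
  ht <- friedman.test(m)
  stat <- unname(ht$statistic)
  p <- ht$p.value
  if (!is.finite(stat)) { # fully tied ranks (identical columns)
    stat <- 0; p <- 1
  }
  new_stat_result(
    test = "friedman", statistic = stat,
    df1 = unname(ht$parameter), df2 = NA_real_, p = p,
    effect = NA_real_, effect_type = NA_character_, n = nrow(m)
  )
}

#' Bonferroni correction
#'
#' `p_corrected = min(1, m * p)`; `m` defaults to the family size, i.e.
#' the number of p values supplied (for the one-sample E-score tests the
#' family is the four emotion comparisons).
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @param m Number of comparisons (>= 1).
#' @return Corrected p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) abort("`m` must be at least 1.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1].")
  pmin(1, m * p)
}

#' Repeated-measures ANOVA with sphericity handling
#'
#' Fully within-subject ANOVA for up to three crossed factors on a
#' complete balanced design, computed through the multivariate linear
#' model route (type-III sums of squares). For every effect whose
#' numerator has more than one degree of freedom, Mauchly's sphericity
#' test is run; when it rejects (p below `sphericity_alpha`) the
#' Greenhouse-Geisser epsilon-adjusted degrees of freedom and p value are
#' reported alongside the uncorrected ones. Partial eta squared is
#' computed from F and the uncorrected degrees of freedom. Effects with
#' zero effect and error sums of squares (constant cells) report F = 0.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns (1-3).
#' @param subject Name of the subject id column.
#' @param sphericity_alpha Mauchly p-value threshold that triggers the
#'   Greenhouse-Geisser correction.
#' @return A `stat_result` tibble with one row per effect: `statistic`
#'   (F), `df1`, `df2`, `p` (uncorrected), `mauchly_w`, `mauchly_p`,
#'   `gg_epsilon`, `df1_adj`, `df2_adj`, `p_adj` (Greenhouse-Geisser
#'   adjusted where triggered, otherwise equal to `p`), `correction`,
#'   `effect` (partial eta squared).
#' @export
rm_anova <- function(data, dv, within, subject = "participant",
                     sphericity_alpha = 0.05) {
  if (length(within) < 1 || length(within) > 3) {
    abort("`within` must name 1 to 3 factors.")
  }
  df <- as.data.frame(data)[, c(subject, within, dv)]
  if (anyNA(df[[dv]])) abort("Missing cells are not allowed in a repeated-measures ANOVA.")
  for (w in within) df[[w]] <- factor(df[[w]])
  df[[subject]] <- factor(df[[subject]])
  counts <- table(df[, c(subject, within)])
  if (any(counts != 1)) {
    abort("The design must be complete and balanced: exactly one observation per subject and factor cell.")
  }

  idata <- rev(expand.grid(rev(lapply(df[within], levels))))
  names(idata) <- within
  wide <- tidyr::pivot_wider(
    df,
    id_cols = dplyr::all_of(subject),
    names_from = dplyr::all_of(within),
    values_from = dplyr::all_of(dv),
    names_sep = "\x01"
  )
  cell_names <- do.call(paste, c(idata, sep = "\x01"))
  Y <- as.matrix(wide[, cell_names])

  effects <- character(0)
  for (k in seq_along(within)) {
    effects <- c(effects, apply(utils::combn(within, k), 2, paste, collapse = ":"))
  }

  if (all(abs(sweep(Y, 1, rowMeans(Y))) < 1e-12)) {
    # Constant within subject: every within-effect F is 0 by convention.
    return(new_stat_result(
      test = "rm anova", effect_name = effects,
      statistic = 0, df1 = NA_real_, df2 = NA_real_, p = 1,
      mauchly_w = NA_real_, mauchly_p = NA_real_, gg_epsilon = NA_real_,
      df1_adj = NA_real_, df2_adj = NA_real_, p_adj = 1,
      correction = "none", effect = 0, effect_type = "partial eta squared"
    ))
  }

  mod <- stats::lm(Y ~ 1)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      # Huynh-Feldt epsilon above 1 is clamped by car; expected, not news.
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })

  uni <- s$univariate.tests
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  rows <- purrr::map_dfr(effects, function(eff) {
    f <- uni[eff, "F value"]; df1 <- uni[eff, "num Df"]; df2 <- uni[eff, "den Df"]
    p <- uni[eff, "Pr(>F)"]
    ss_eff <- uni[eff, "Sum Sq"]; ss_err <- uni[eff, "Error SS"]
    if (!is.finite(f)) { f <- 0; p <- 1 }
    mw <- mp <- eps <- NA_real_
    if (!is.null(sph) && eff %in% rownames(sph)) {
      mw <- sph[eff, "Test statistic"]; mp <- sph[eff, "p-value"]
    }
    if (!is.null(adj) && eff %in% rownames(adj)) eps <- adj[eff, "GG eps"]
    corrected <- is.finite(mp) && mp < sphericity_alpha && is.finite(eps)
    tibble(
      test = "rm anova", effect_name = eff,
      statistic = f, df1 = df1, df2 = df2, p = p,
      ss_effect = ss_eff, ss_error = ss_err,
      mauchly_w = mw, mauchly_p = mp, gg_epsilon = eps,
      df1_adj = if (corrected) df1 * eps else df1,
      df2_adj = if (corrected) df2 * eps else df2,
      p_adj = if (corrected) adj[eff, "Pr(>F[GG])"] else p,
      correction = if (corrected) "greenhouse-geisser" else "none",
      effect = partial_eta_sq(f, df1, df2),
      effect_type = "partial eta squared"
    )
  })
  class(rows) <- c("stat_result", class(rows))
  rows
}

#' @export
tidy.stat_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stat_result")
  out
}

#' @export
glance.stat_result <- function(x, ...) {
  tibble(n_tests = nrow(x), min_p = min(x$p), tests = paste(unique(x$test), collapse = ", "))
}
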