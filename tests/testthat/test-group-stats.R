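test_that("one-sample t matches the textbook formula", {
  v <- c(2, -1, 3, 0, 1) # mean 1, sd sqrt(2.5)
  r <- one_sample_t(v)
  t_hand <- 1 / (sqrt(2.5) / sqrt(5))
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$statistic, sqrt(2), tolerance = 1e-12)
  p_hand <- 2 * (1 - pt(t_hand, 4))
  expect_equal(r$p, p_hand, tolerance = 1e-12)
  expect_equal(r$effect, r$statistic / sqrt(5), tolerance = 1e-15)

  expect_error(one_sample_t(c(1, 1, 1)), "Zero variance")
  expect_error(one_sample_t(c(1)), "at least two")
})

test_that("paired t is the one-sample t on differences", {
  a <- c(5, 7, 6, 9); b <- c(4, 7, 4, 6)
  r <- paired_t(a, b)
  expect_equal(r$statistic, one_sample_t(a - b)$statistic)
  expect_error(paired_t(a, a), "Zero variance")
  expect_error(paired_t(a, b[1:3]), "equal length")
})

test_that("effect-size identities hold for every output", {
  set.seed(7)
  for (i in 1:20) {
    v <- rnorm(sample(5:40, 1))
    r <- one_sample_t(v)
    expect_equal(r$effect * sqrt(r$n), r$statistic, tolerance = 1e-12)
    w <- wilcoxon_signed_rank(v)
    expect_equal(w$effect * sqrt(w$n), w$statistic, tolerance = 1e-12)
  }
})

test_that("signed-rank Z matches the no-continuity normal approximation", {
  # all-positive differences, no ties: Z = mu_W / sigma_W
  v10 <- 1:10
  r10 <- wilcoxon_signed_rank(v10)
  expect_equal(r10$statistic, 27.5 / sqrt(96.25), tolerance = 1e-12)
  expect_equal(round(r10$statistic, 3), 2.803)
  expect_equal(round(r10$effect, 3), 0.886)

  v13 <- 1:13
  r13 <- wilcoxon_signed_rank(v13)
  expect_equal(round(r13$statistic, 3), 3.180)
  expect_equal(round(r13$effect, 3), 0.882)

  # p agrees with the reference implementation
  set.seed(8)
  x <- rnorm(15, 0.4)
  mine <- wilcoxon_signed_rank(x)
  ref <- suppressWarnings(wilcox.test(x, mu = 0, exact = FALSE, correct = FALSE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  mine_cc <- wilcoxon_signed_rank(x, correct = TRUE)
  ref_cc <- suppressWarnings(wilcox.test(x, mu = 0, exact = FALSE, correct = TRUE))
  expect_equal(mine_cc$p, ref_cc$p.value, tolerance = 1e-10)

  # symmetry: equal positive and negative ranks cancel (small n warns
  # about the normal approximation)
  expect_warning(z0 <- wilcoxon_signed_rank(c(-2, -1, 1, 2))$statistic,
                 "normal approximation")
  expect_equal(z0, 0)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  # zero differences are dropped from n
  r <- wilcoxon_signed_rank(c(0, 0, 1:10))
  expect_equal(r$n, 10)
})

test_that("Friedman test matches hand-ranked oracles", {
  same <- matrix(rep(c(1, 2, 3), 3), 3, byrow = TRUE)
  same[, 1] <- same[, 2] <- same[, 3] <- 5
  expect_equal(friedman_rank_test(same)$statistic, 0)

  # strict identical ordering per subject: chi2 = 6 with df 2
  ord <- matrix(c(1, 2, 3, 2, 4, 6, 1, 5, 9), 3, byrow = TRUE)
  r <- friedman_rank_test(ord)
  expect_equal(r$statistic, 6)
  expect_equal(r$df1, 2)

  # two conditions: direction agrees with the signed-rank test
  two <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 3, 5, 6, 7))
  fr <- friedman_rank_test(two)
  wz <- wilcoxon_signed_rank(two[, "b"] - two[, "a"])
  expect_lt(fr$p, 0.05)
  expect_gt(wz$statistic, 0)

  expect_error(friedman_rank_test(matrix(c(1, NA, 2, 3), 2)), "Missing")
})

test_that("Bonferroni correction multiplies and clamps", {
  expect_equal(bonferroni(0.012, 4), 0.048)
  expect_equal(bonferroni(0.4, 4), 1.0)
  expect_equal(bonferroni(c(0.2, 0.01)), c(0.4, 0.02))
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(0.1, 0), "at least 1")
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
})

# Brute-force repeated-measures oracle: explicit sums of squares.
oracle_rm_1way <- function(Y) { # subjects x conditions
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  cond <- colMeans(Y); subj <- rowMeans(Y)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (cond[j] - grand)^2
  ss_err <- 0
  for (i in 1:n) for (j in 1:k) {
    ss_err <- ss_err + (Y[i, j] - subj[i] - cond[j] + grand)^2
  }
  f <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(ss_cond = ss_cond, ss_err = ss_err, f = f,
       df1 = k - 1, df2 = (n - 1) * (k - 1))
}

test_that("one-way rm ANOVA matches the explicit-loop oracle to 1e-10", {
  set.seed(9)
  Y <- matrix(rnorm(15, mean = rep(c(0, 1, 0.5), each = 5)), 5, 3)
  long <- tibble::tibble(
    participant = rep(1:5, 3),
    cond = rep(c("a", "b", "c"), each = 5),
    y = as.vector(Y))
  r <- rm_anova(long, "y", "cond")
  o <- oracle_rm_1way(Y)
  expect_equal(r$statistic, unname(o$f), tolerance = 1e-10)
  expect_equal(r$ss_effect, unname(o$ss_cond), tolerance = 1e-10)
  expect_equal(r$ss_error, unname(o$ss_err), tolerance = 1e-10)
  expect_equal(r$df1, o$df1)
  expect_equal(r$df2, o$df2)
  expect_equal(r$p, 1 - pf(o$f, o$df1, o$df2), tolerance = 1e-10)
  expect_equal(r$effect, o$ss_cond / (o$ss_cond + o$ss_err), tolerance = 1e-10)
})

test_that("sphericity handling adjusts degrees of freedom coherently", {
  set.seed(10)
  n <- 12
  # strongly non-spherical: one condition much more variable
  Y <- cbind(rnorm(n, 0, 0.2), rnorm(n, 0.5, 0.2), rnorm(n, 1, 3))
  long <- tibble::tibble(participant = rep(1:n, 3),
                         cond = rep(c("a", "b", "c"), each = n),
                         y = as.vector(Y))
  r <- rm_anova(long, "y", "cond")
  expect_true(is.finite(r$mauchly_p))
  expect_true(r$gg_epsilon > 1 / (3 - 1) - 1e-9 && r$gg_epsilon <= 1)
  if (r$mauchly_p < 0.05) {
    expect_equal(r$correction, "greenhouse-geisser")
    expect_equal(r$df1_adj, r$df1 * r$gg_epsilon)
    expect_equal(r$df2_adj, r$df2 * r$gg_epsilon)
    expect_equal(r$p_adj, 1 - pf(r$statistic, r$df1_adj, r$df2_adj),
                 tolerance = 1e-10)
    expect_gte(r$p_adj, r$p)
  }
  expect_lte(r$df1_adj, r$df1)
  expect_lte(r$df2_adj, r$df2)
})

test_that("multi-factor designs report every effect with eta_p^2", {
  set.seed(11)
  grid <- tidyr::expand_grid(participant = 1:8,
                             f1 = c("x", "y"),
                             f2 = c("p", "q", "r"))
  grid$y <- rnorm(nrow(grid)) + as.numeric(grid$f1 == "y") * 0.5
  r <- rm_anova(grid, "y", c("f1", "f2"))
  expect_equal(r$effect_name, c("f1", "f2", "f1:f2"))
  expect_equal(r$effect,
               r$statistic * r$df1 / (r$statistic * r$df1 + r$df2),
               tolerance = 1e-12)
  # two-level factor skips sphericity
  expect_true(is.na(r$mauchly_p[r$effect_name == "f1"]))
})

test_that("degenerate inputs are handled as contracted", {
  # all cells equal within subject: every F is 0
  grid <- tidyr::expand_grid(participant = 1:5, cond = c("a", "b", "c"))
  grid$y <- as.numeric(grid$participant) # varies only between subjects
  r <- rm_anova(grid, "y", "cond")
  expect_true(all(r$statistic == 0))
  expect_true(all(r$p_adj == 1))

  # missing cells error
  bad <- grid[-1, ]
  expect_error(rm_anova(bad, "y", "cond"), "complete and balanced")
})

test_that("the one-sample t keeps its type-I error near the nominal level", {
  set.seed(12)
  n_sim <- 1000
  rejections <- 0
  for (i in seq_len(n_sim)) {
    p <- one_sample_t(rnorm(20))$p
    if (p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
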