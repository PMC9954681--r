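# Statistical procedures: summary t tests, chi-square, ANOVA + post hoc,
# correlation, Cronbach's alpha, LOWESS.

test_that("summary t equals the raw-data t test in both variants", {
  set.seed(31)
  x <- rnorm(40, 1, 2); y <- rnorm(55, 0.4, 3)
  sx <- two_sample_summary(length(x), mean(x), sd(x))
  sy <- two_sample_summary(length(y), mean(y), sd(y))
  for (variant in c("pooled", "welch")) {
    ours <- t_test_from_summary(sx, sy, variant)
    ref <- t.test(x, y, var.equal = (variant == "pooled"))
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(ours$parameter), unname(ref$parameter),
                 tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch df never exceeds the pooled df and matches it when balanced", {
  set.seed(32)
  for (i in 1:20) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    a <- two_sample_summary(n1, rnorm(1), runif(1, 0.5, 3))
    b <- two_sample_summary(n2, rnorm(1), runif(1, 0.5, 3))
    w <- t_test_from_summary(a, b, "welch")
    expect_lte(unname(w$parameter), n1 + n2 - 2 + 1e-9)
  }
  a <- two_sample_summary(30, 1, 2); b <- two_sample_summary(30, 0, 2)
  expect_equal(unname(t_test_from_summary(a, b, "welch")$parameter), 58)
})

test_that("equal means give t = 0; degenerate variances error", {
  a <- two_sample_summary(10, 5, 1); b <- two_sample_summary(12, 5, 3)
  expect_equal(unname(t_test_from_summary(a, b, "welch")$statistic), 0)
  z1 <- two_sample_summary(10, 5, 0); z2 <- two_sample_summary(10, 5, 0)
  expect_qeeg_error(t_test_from_summary(z1, z2, "pooled"), "qeeg_stats_error")
})

test_that("chi-square is uncorrected, permutation-invariant and zero at independence", {
  tab <- matrix(c(130, 130, 163, 58), 2)
  res <- chi_square(tab)
  # oracle: direct sum over cells of (O - E)^2 / E
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 1)
  # permuting rows/columns leaves the statistic unchanged
  perm <- chi_square(tab[2:1, 2:1])
  expect_equal(perm$statistic, res$statistic, tolerance = 1e-12)
  # O = E exactly -> 0
  ind <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(chi_square(ind)$statistic, 0, tolerance = 1e-12)
  # raw residual margins vanish
  expect_lt(max(abs(rowSums(tab - res$expected))), 1e-10)
  expect_lt(max(abs(colSums(tab - res$expected))), 1e-10)
  # degenerate margins rejected
  expect_qeeg_error(chi_square(matrix(c(0, 0, 5, 7), 2)), "qeeg_stats_error")
})

test_that("cell comparisons flag the sex imbalance pattern", {
  res <- chi_square(matrix(c(130, 130, 163, 58), 2,
                           dimnames = list(c("F", "M"), c("HC", "MDD"))))
  # all four cells depart from independence beyond |1.96| here
  expect_true(all(res$significant_cells))
  expect_equal(sign(res$stdres["F", "MDD"]), 1)   # more women than expected
  expect_equal(sign(res$stdres["M", "MDD"]), -1)
})

test_that("two-group ANOVA reduces to the squared pooled t", {
  set.seed(33)
  g1 <- rnorm(20); g2 <- rnorm(25, 0.5)
  av <- one_way_anova(list(a = g1, b = g2))
  tt <- t_test_from_summary(two_sample_summary(20, mean(g1), sd(g1)),
                            two_sample_summary(25, mean(g2), sd(g2)),
                            "pooled")
  expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av$df_within, unname(tt$parameter))
  # degenerate: identical constants
  expect_qeeg_error(one_way_anova(list(rep(1, 5), rep(1, 5))),
                    "qeeg_stats_error")
})

test_that("bonferroni post hoc flags only pairs with the shifted group", {
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    groups <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50, 3))
    ph <- bonferroni_posthoc(groups)
    shifted <- ph$group1 == "c" | ph$group2 == "c"
    expect_true(all(ph$significant[shifted]))
    hits <- hits + sum(ph$significant[!shifted])
    expect_true(all(ph$p_adj >= ph$p))
    expect_true(all(ph$p_adj <= 1))
  }
  expect_lte(hits, 1)  # null pair significant at most rarely across seeds
})

test_that("pearson_r matches the direct product-moment formula", {
  x <- c(2, 4, 4.5, 5, 7, 8, 8.2, 9, 11, 15)
  y <- c(1, 3, 5.1, 4, 6, 9, 7.5, 8, 12, 13)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 7)$r, -1)
  expect_qeeg_error(pearson_r(x, rep(1, 10)), "qeeg_stats_error")
  expect_qeeg_error(pearson_r(1:2, 1:2), "qeeg_stats_error")
})

test_that("cronbach alpha equals the brute-force formula on a hand matrix", {
  m <- matrix(c(3, 5, 1, 4,
                4, 6, 2, 5,
                2, 6, 1, 3), nrow = 4)
  k <- ncol(m)
  alpha_direct <- k / (k - 1) *
    (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), alpha_direct, tolerance = 1e-12)
})

test_that("cronbach alpha: perfect consistency, independence, shift invariance", {
  v <- c(1, 5, 2, 8, 3, 7)
  expect_equal(cronbach_alpha(cbind(v, v, v)), 1, tolerance = 1e-12)
  set.seed(34)
  m <- matrix(rnorm(3 * 4000), ncol = 3)  # independent items
  expect_lt(abs(cronbach_alpha(m)), 0.1)
  m2 <- cbind(v, v + 10, v - 3)
  expect_equal(cronbach_alpha(m2), 1, tolerance = 1e-12)
  expect_qeeg_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))),
                    "qeeg_stats_error")
})

test_that("lowess trend is exact on lines, constant on constants", {
  x <- seq(20, 70, length.out = 40)
  y <- 3 - 0.05 * x
  sm <- lowess_trend(x, y, fraction = 0.5)
  expect_equal(sm$fitted, 3 - 0.05 * sm$x, tolerance = 1e-6)
  smc <- lowess_trend(x, rep(2, 40))
  expect_true(all(abs(smc$fitted - 2) < 1e-12))
  # noisy quadratic stays within the noise level
  set.seed(35)
  xx <- runif(300, 0, 1)
  yy <- (xx - 0.5)^2 + rnorm(300, sd = 0.05)
  smq <- lowess_trend(xx, yy, fraction = 0.3)
  expect_lt(max(abs(smq$fitted - (smq$x - 0.5)^2)), 0.05)
  expect_qeeg_error(lowess_trend(x, y, fraction = 1.5), "qeeg_config_error")
  expect_qeeg_error(lowess_trend(1:4, 1:4), "qeeg_stats_error")
})
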