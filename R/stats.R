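# Cohort-level statistics: summary t tests, chi-square with cell-wise
# comparisons, one-way ANOVA with Bonferroni post hoc, Pearson r,
# Cronbach's alpha and LOWESS age trends.

#' Two-sample summary
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group sample standard deviation (>= 0).
#' @return A `two_sample_summary` list.
#' @export
two_sample_summary <- function(n, mean, sd) {
  if (n < 2 || sd < 0 || !is.finite(mean)) {
    qeeg_error("summary needs n >= 2, finite mean, sd >= 0",
               "qeeg_stats_error")
  }
  structure(list(n = n, mean = mean, sd = sd), class = "two_sample_summary")
}

#' Two-sample t test from group summaries
#'
#' Pooled: t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2)) on n1 + n2 - 2 df.
#' Welch: t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite
#' fractional df. p is two-sided.
#'
#' @param a,b [two_sample_summary()] objects (or lists with `n`, `mean`,
#'   `sd`).
#' @param variant "pooled" or "welch".
#' @return List of class `htest` with `statistic` (t), `parameter` (df)
#'   and `p.value`.
#' @export
t_test_from_summary <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  v1 <- a$sd^2; v2 <- b$sd^2
  if (variant == "pooled") {
    sp2 <- ((a$n - 1) * v1 + (b$n - 1) * v2) / (a$n + b$n - 2)
    if (sp2 <= 0) {
      if (a$mean == b$mean) {
        qeeg_error("zero pooled variance with equal means: t undefined",
                   "qeeg_stats_error")
      }
      sp2 <- 0
    }
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    se <- sqrt(v1 / a$n + v2 / b$n)
    if (se == 0 && a$mean == b$mean) {
      qeeg_error("zero variances with equal means: t undefined",
                 "qeeg_stats_error")
    }
    df <- (v1 / a$n + v2 / b$n)^2 /
      ((v1 / a$n)^2 / (a$n - 1) + (v2 / b$n)^2 / (b$n - 1))
  }
  tval <- if (a$mean == b$mean) 0 else (a$mean - b$mean) / se
  p <- 2 * stats::pt(-abs(tval), df)
  structure(
    list(statistic = c(t = tval), parameter = c(df = df), p.value = p,
         method = sprintf("Two-sample t test from summaries (%s)", variant),
         data.name = "group summaries"),
    class = "htest"
  )
}

#' Pearson chi-square with adjusted standardized residuals
#'
#' Uncorrected Pearson chi-square on an r x c contingency table (no Yates
#' continuity correction unless asked for), plus the adjusted standardized
#' residuals used for cell-wise comparisons: cells with |residual| > 1.96
#' differ from independence at the 5% level.
#'
#' @param table matrix of non-negative integer counts, at least 2 x 2.
#' @param correction apply the Yates continuity correction (2 x 2 only).
#' @return List with `statistic`, `df`, `p.value`, `expected`, `stdres`
#'   (adjusted standardized residuals) and `significant_cells`
#'   (|stdres| > 1.96).
#' @export
chi_square <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2 || any(table < 0)) {
    qeeg_error("need an r x c (r, c >= 2) table of non-negative counts",
               "qeeg_stats_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    qeeg_error("degenerate table: a zero row or column margin",
               "qeeg_stats_error")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correction))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = ht$expected, stdres = ht$stdres,
       significant_cells = abs(ht$stdres) > stats::qnorm(0.975))
}

#' One-way between-subjects ANOVA
#'
#' @param groups named list of numeric samples, each of size >= 2.
#' @return List with `F`, `df_between`, `df_within`, `p.value` and the
#'   group means.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, 0L) < 2)) {
    qeeg_error("need >= 2 groups with n >= 2 each", "qeeg_stats_error")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  k <- length(groups); n <- length(y)
  gm <- tapply(y, g, mean)
  ss_b <- sum(tapply(y, g, length) * (gm - mean(y))^2)
  ss_w <- sum((y - gm[g])^2)
  if (ss_w <= 0) {
    qeeg_error("zero within-group variance: F undefined", "qeeg_stats_error")
  }
  Fval <- (ss_b / (k - 1)) / (ss_w / (n - k))
  list(F = Fval, df_between = k - 1, df_within = n - k,
       p.value = stats::pf(Fval, k - 1, n - k, lower.tail = FALSE),
       group_means = gm)
}

#' Bonferroni post hoc pairwise comparisons
#'
#' All pairwise pooled two-sample t tests with each p multiplied by the
#' number of comparisons (capped at 1).
#'
#' @param groups named list of numeric samples.
#' @param alpha significance level applied to the adjusted p.
#' @return Data frame with one row per pair: `group1`, `group2`, `t`,
#'   `df`, `p`, `p_adj`, `significant`.
#' @export
bonferroni_posthoc <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) qeeg_error("need >= 2 groups", "qeeg_stats_error")
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x <- groups[[i1]]; y <- groups[[i2]]
    ht <- t_test_from_summary(
      two_sample_summary(length(x), mean(x), stats::sd(x)),
      two_sample_summary(length(y), mean(y), stats::sd(y)),
      variant = "pooled"
    )
    data.frame(group1 = nm[i1], group2 = nm[i2],
               t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value, p_adj = min(1, ht$p.value * m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and the two-sided `p.value` (t transform).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    qeeg_error("need equal-length vectors of at least 3 points",
               "qeeg_stats_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    qeeg_error("zero variance: correlation undefined", "qeeg_stats_error")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p.value = ht$p.value)
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of case
#' totals), with sample (n-1) variances. Cases are participants, items
#' are (for the central-electrode reliability check) the C3/Cz/C4 powers
#' of one band.
#'
#' @param m numeric matrix, cases x items: >= 3 cases, >= 2 items, no
#'   missing cells.
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2 || nrow(m) < 3 || anyNA(m)) {
    qeeg_error("need a complete cases x items matrix (>= 3 x >= 2)",
               "qeeg_stats_error")
  }
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) {
    qeeg_error("zero total-score variance: alpha undefined",
               "qeeg_stats_error")
  }
  item_var <- sum(apply(m, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' LOWESS age trend
#'
#' Locally weighted scatterplot smoothing (tricube-weighted local linear
#' fit) of a value against age, evaluated at the sorted ages.
#'
#' @param x predictor (ages).
#' @param y response (powers).
#' @param fraction smoother span in (0, 1].
#' @param iterations robustness iterations (0 = plain local regression).
#' @return Data frame with columns `x` (sorted) and `fitted`.
#' @export
lowess_trend <- function(x, y, fraction = 2 / 3, iterations = 3) {
  if (length(x) != length(y) || length(x) < 5) {
    qeeg_error("need >= 5 paired points", "qeeg_stats_error")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    qeeg_error("fraction must lie in (0, 1]", "qeeg_config_error")
  }
  sm <- stats::lowess(x, y, f = fraction, iter = iterations)
  data.frame(x = sm$x, fitted = sm$y)
}
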