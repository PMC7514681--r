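# Nonparametric repeated-measures statistics with effect sizes.
#
# All three tests return a common `group_test` record so the pipeline can
# emit one tidy stats table: test name, statistic, n used by the effect-size
# formula, df where applicable, raw and (optionally) Bonferroni-corrected p,
# and the effect size r.

group_test <- function(test_name, statistic, n, df = NA_integer_,
                       p_raw, effect_size, note = NA_character_) {
  structure(list(test_name = test_name, statistic = statistic, n = n,
                 df = df, p_raw = p_raw, p_corrected = NA_real_,
                 effect_size = effect_size, note = note),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, n = %d%s, p = %.4g%s, r = %.2f\n",
              x$test_name, x$statistic, x$n,
              if (is.na(x$df)) "" else sprintf(", df = %d", x$df),
              x$p_raw,
              if (is.na(x$p_corrected)) "" else sprintf(" (corrected %.4g)", x$p_corrected),
              x$effect_size))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Friedman rank test across conditions
#'
#' Rank-based repeated-measures test of a condition effect: values are
#' ranked within each participant (row), and the chi-square statistic with
#' `k - 1` degrees of freedom tests whether the column rank sums differ.
#' Average ranks are used for ties, with the standard tie correction in the
#' denominator.  Rows containing missing values are dropped (listwise).
#'
#' The effect size is r = sqrt(chi2 / N) with N the total number of
#' observations entering the test (complete rows x conditions).
#'
#' @param data participants x conditions numeric matrix.
#' @return A `group_test` with the chi-square statistic, df, p, and r.
#' @export
friedman_test <- function(data) {
  data <- as.matrix(data)
  if (ncol(data) < 2) stop_invalid("need at least 2 conditions")
  complete <- stats::complete.cases(data)
  data <- data[complete, , drop = FALSE]
  n <- nrow(data); k <- ncol(data)
  if (n < 2) stop_invalid("need at least 2 complete participant rows")
  r <- t(apply(data, 1, rank))
  Rj <- colSums(r)
  tie_term <- sum(apply(data, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  # denom hits 0 only when every row is fully tied: no rank information
  chi2 <- if (denom <= 0) 0 else 12 * sum((Rj - n * (k + 1) / 2)^2) / denom
  df <- k - 1
  N <- n * k
  group_test("friedman", chi2, n = N, df = as.integer(df),
             p_raw = stats::pchisq(chi2, df, lower.tail = FALSE),
             effect_size = effect_size_friedman(chi2, N))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test on `data_a - data_b`.  Zero differences are dropped
#' (the standard convention); absolute differences are ranked with average
#' ranks for ties.  The statistic is reported as the standardized Z of the
#' positive-rank sum (normal approximation with tie correction); for fewer
#' than 20 non-zero differences without ties the exact signed-rank
#' distribution supplies the p-value instead of the normal tail.
#'
#' The effect size is r = |Z| / sqrt(N) with N the number of paired
#' observations contributing (non-zero differences).
#'
#' @param data_a,data_b paired numeric vectors of equal length.
#' @return A `group_test` with Z, n, p and r.  If every difference is zero
#'   the result is degenerate: Z = 0, p = 1, r = 0.
#' @export
wilcoxon_pair <- function(data_a, data_b) {
  if (length(data_a) != length(data_b))
    stop_invalid("paired vectors must have equal length")
  keep <- is.finite(data_a) & is.finite(data_b)
  d <- data_a[keep] - data_b[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(group_test("wilcoxon_signed_rank", 0, n = 0L, p_raw = 1,
                      effect_size = 0, note = "degenerate: all differences zero"))
  if (n < 5)
    stop_invalid("need at least 5 non-zero differences (have %d)", n)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu) / sqrt(sigma2)
  has_ties <- any(ties > 1)
  p <- if (n < 20 && !has_ties) {
    min(1, 2 * min(stats::psignrank(V, n), stats::psignrank(V - 1, n, lower.tail = FALSE)))
  } else {
    2 * stats::pnorm(-abs(z))
  }
  group_test("wilcoxon_signed_rank", z, n = as.integer(n), p_raw = p,
             effect_size = effect_size_wilcoxon(z, n))
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks, with a two-sided p-value from
#' the asymptotic t approximation, `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#' Pairs with a missing value are dropped (pairwise deletion).
#'
#' @param x,y numeric vectors of equal length; at least 4 complete pairs.
#' @return A `group_test` with rho as both statistic and effect size.  When
#'   either variable has zero rank variance the result is degenerate and
#'   flagged in `note` with `rho = NA`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop_invalid("need at least 4 complete pairs (have %d)", n)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(group_test("spearman", NA_real_, n = as.integer(n), p_raw = NA_real_,
                      effect_size = NA_real_, note = "degenerate: zero rank variance"))
  rho <- cor(rx, ry)
  p <- if (abs(rho) == 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  group_test("spearman", rho, n = as.integer(n), df = as.integer(n - 2),
             p_raw = p, effect_size = rho)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons `k` and caps at 1.
#'
#' @param p_values numeric vector of raw p-values.
#' @param k number of comparisons (default: `length(p_values)`).
#' @return Corrected p-values.
#' @export
bonferroni <- function(p_values, k = length(p_values)) {
  if (k < 1) stop_invalid("k must be >= 1")
  pmin(1, p_values * k)
}

#' Effect size for the Friedman test
#'
#' r = sqrt(chi2 / N), where N is the total number of observations.
#'
#' @param chisq Friedman chi-square statistic.
#' @param n total observation count.
#' @return Effect size in \[0, 1\] (values above 1 are impossible for valid
#'   inputs).
#' @export
effect_size_friedman <- function(chisq, n) {
  if (chisq < 0 || n <= 0) stop_invalid("chisq must be >= 0 and n > 0")
  sqrt(chisq / n)
}

#' Effect size for the Wilcoxon signed-rank test
#'
#' r = |Z| / sqrt(N), Z the standardized signed-rank statistic.
#'
#' @param z standardized test statistic.
#' @param n number of paired observations contributing.
#' @return Effect size in \[0, 1\] for plausible Z.
#' @export
effect_size_wilcoxon <- function(z, n) {
  if (n <= 0) stop_invalid("n must be > 0")
  abs(z) / sqrt(n)
}
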