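#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (the standard tie convention). Thin
#' wrapper over [stats::cor()] with the argument checks the analysis pipeline
#' relies on: both vectors must be non-constant so the coefficient is defined.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A single correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Fisher-z confidence interval for a correlation
#'
#' `tanh(atanh(r) +/- z * 1/sqrt(n - 3))`. Applied in this package to Spearman
#' coefficients as well as Pearson ones; with r = 0.57 and n = 18 it gives
#' (0.14, 0.82) to two decimals.
#'
#' @param r Correlation estimate, |r| <= 1.
#' @param n Number of paired observations (>= 4).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return List with `low`, `high`, `level`; degenerate at r when |r| = 1.
#' @export
fisher_z_ci <- function(r, n, level = 0.95) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), abs(r) <= 1,
            n >= 4, level > 0, level < 1)
  if (abs(r) == 1) {
    return(list(low = r, high = r, level = level))
  }
  z <- atanh(r)
  hw <- stats::qnorm((1 + level) / 2) / sqrt(n - 3)
  list(low = tanh(z - hw), high = tanh(z + hw), level = level)
}

# Correlation between two correlation estimates sharing variable 1
# (r12 and r13), used by Zou's overlapping-dependent-correlations interval.
corr_of_correlations <- function(r12, r13, r23) {
  num <- (r23 - 0.5 * r12 * r13) * (1 - r12^2 - r13^2 - r23^2) + r23^3
  den <- (1 - r12^2) * (1 - r13^2)
  num / den
}

#' Zou's confidence interval for a difference of dependent correlations
#'
#' Modified-asymptotic interval for `rho12 - rho13` when the two correlations
#' share variable 1 (the overlapping case): the individual Fisher-z limits are
#' combined with a covariance correction that uses the correlation `r23`
#' between the two non-shared variables.
#'
#' @param r12,r13 The two correlations being compared.
#' @param r23 Correlation between the non-shared variables.
#' @param n Sample size (>= 4).
#' @param level Confidence level, default 0.95.
#' @return List with `low`, `high`, `level`, `estimate` (= r12 - r13).
#' @export
zou_diff_ci <- function(r12, r13, r23, n, level = 0.95) {
  stopifnot(abs(r12) <= 1, abs(r13) <= 1, abs(r23) <= 1, n >= 4,
            level > 0, level < 1)
  det3 <- 1 + 2 * r12 * r13 * r23 - r12^2 - r13^2 - r23^2
  if (det3 < -1e-8) stop("correlations do not form a positive semidefinite matrix")
  ci1 <- fisher_z_ci(r12, n, level)
  ci2 <- fisher_z_ci(r13, n, level)
  # at |r| = 1 the Fisher interval is degenerate and the covariance term
  # multiplies a zero half-width, so the dependency correction drops out
  rc <- if (abs(r12) == 1 || abs(r13) == 1) 0 else
    corr_of_correlations(r12, r13, r23)
  est <- r12 - r13
  low <- est - sqrt((r12 - ci1$low)^2 + (ci2$high - r13)^2 -
                      2 * rc * (r12 - ci1$low) * (ci2$high - r13))
  high <- est + sqrt((ci1$high - r12)^2 + (r13 - ci2$low)^2 -
                       2 * rc * (ci1$high - r12) * (r13 - ci2$low))
  list(low = low, high = high, level = level, estimate = est)
}

#' Exact two-sided binomial test p-value
#'
#' Small-probability summation: the p-value is the sum of all outcome
#' probabilities not exceeding that of the observed count, under
#' Binomial(n, p0). At p0 = 0.5 this equals the doubled one-tail probability
#' capped at 1. Wraps [stats::binom.test()].
#'
#' @param k Observed count of successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability, default 0.5.
#' @return p-value in (0, 1\].
#' @export
binom_test_exact <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, n >= 1, p0 >= 0, p0 <= 1)
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Theil-Sen robust line
#'
#' Slope is the median of all pairwise slopes over pairs with distinct x;
#' intercept is `median(y - slope * x)`. Exact on noiseless linear input and
#' resistant to isolated outliers; used here to detrend within-trial drift in
#' glance-onset series.
#'
#' @param x,y Numeric vectors of equal length with at least 2 distinct x.
#' @return List with `slope` and `intercept`.
#' @export
theil_sen <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2L, !anyNA(x), !anyNA(y))
  if (length(unique(x)) < 2L) stop("all x values identical")
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  slope <- stats::median(dy[keep] / dx[keep])
  list(slope = slope, intercept = stats::median(y - slope * x))
}

#' Passing-Bablok symmetric regression
#'
#' Nonparametric errors-in-both-variables line fit: pairwise slopes are formed
#' for all point pairs with distinct x, slopes equal to -1 are discarded, and
#' the estimate is the median order statistic shifted by K, the number of
#' slopes below -1 (which makes the estimator symmetric:
#' `slope(x, y) = 1/slope(y, x)` on tie-free data). The slope confidence
#' interval uses the standard normal-approximation rank bounds; the intercept
#' is `median(y - slope * x)`.
#'
#' @param x,y Numeric vectors (>= 3 points, >= 2 distinct x).
#' @param level Confidence level for the slope interval, default 0.95.
#' @return List with `slope`, `intercept`, `slope_ci` (list low/high/level),
#'   `n_pairs` (points) and `n_slopes` (pairwise gradients used).
#' @export
passing_bablok <- function(x, y, level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L, !anyNA(x), !anyNA(y), level > 0, level < 1)
  if (length(unique(x)) < 2L) stop("all x values identical")
  n <- length(x)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  s <- dy[keep] / dx[keep]
  s <- s[s != -1]
  s <- sort(s)
  N <- length(s)
  if (N == 0L) stop("no usable pairwise slopes")
  K <- sum(s < -1)
  # shifted median: offset by K so that slopes below -1 are balanced against
  # the implicit slopes at +/- infinity (symmetry of the estimator)
  slope <- if (N %% 2L == 1L) {
    s[(N + 1L) %/% 2L + K]
  } else {
    mean(s[c(N %/% 2L + K, N %/% 2L + 1L + K)])
  }
  w <- stats::qnorm((1 + level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - w) / 2)
  M2 <- N - M1 + 1L
  lo <- if (M1 + K >= 1L && M1 + K <= N) s[M1 + K] else -Inf
  hi <- if (M2 + K >= 1L && M2 + K <= N) s[M2 + K] else Inf
  list(slope = slope,
       intercept = stats::median(y - slope * x),
       slope_ci = list(low = lo, high = hi, level = level),
       n_pairs = n,
       n_slopes = N)
}

#' Ordinary least squares with a joint parameter-region test
#'
#' Simple linear regression of y on x with t-based marginal confidence
#' intervals and an F-based joint test of a hypothesised (slope0, intercept0),
#' used to ask whether a reference line (such as the identity) lies inside the
#' joint confidence region of the fit.
#'
#' @param x,y Numeric vectors (>= 3 points, non-constant x).
#' @param level Confidence level, default 0.95.
#' @param slope0,intercept0 Reference line for the joint test, default the
#'   identity line (slope 1, intercept 0).
#' @return List with `slope`, `intercept`, `r_squared`, `slope_ci`,
#'   `intercept_ci`, `f_stat`, `f_crit`, `p_joint` and `inside` (TRUE when the
#'   reference line is not rejected at `level`).
#' @export
ols_fit <- function(x, y, level = 0.95, slope0 = 1, intercept0 = 0) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L, !anyNA(x), !anyNA(y))
  if (stats::var(x) == 0) stop("degenerate fit: x has zero variance")
  n <- length(x)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  ci <- stats::confint(fit, level = level)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  rss0 <- sum((y - intercept0 - slope0 * x)^2)
  dfree <- n - 2L
  if (rss == 0) {
    f_stat <- if (rss0 == 0) 0 else Inf
  } else {
    f_stat <- ((rss0 - rss) / 2) / (rss / dfree)
  }
  f_crit <- stats::qf(level, 2, dfree)
  list(slope = unname(cf["x"]),
       intercept = unname(cf["(Intercept)"]),
       r_squared = r2,
       slope_ci = list(low = ci["x", 1], high = ci["x", 2], level = level),
       intercept_ci = list(low = ci["(Intercept)", 1],
                           high = ci["(Intercept)", 2], level = level),
       f_stat = f_stat,
       f_crit = f_crit,
       p_joint = stats::pf(f_stat, 2, dfree, lower.tail = FALSE),
       inside = f_stat <= f_crit)
}
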