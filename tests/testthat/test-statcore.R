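test_that("spearman_rho matches explicit average-rank computation", {
  x <- c(3, 1, 4, 2, 5)
  expect_equal(spearman_rho(x, x * 2 + 1), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # tied case frozen from hand-ranking: ranks of (2,2,5,4) are (1.5,1.5,4,3)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 2, 5, 4)), 3.5 / sqrt(22.5))
  set.seed(41)
  for (i in 1:50) {
    x <- sample(1:6, 10, replace = TRUE)
    y <- sample(1:6, 10, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y), bf_spearman(x, y), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("fisher_z_ci reproduces the published interval and basic shapes", {
  ci <- fisher_z_ci(0.57, 18)
  expect_equal(round(ci$low, 2), 0.14)
  expect_equal(round(ci$high, 2), 0.82)
  ci0 <- fisher_z_ci(0, 20)
  expect_equal(ci0$low, -ci0$high)
  expect_lt(fisher_z_ci(0.3, 1e6)$high - fisher_z_ci(0.3, 1e6)$low, 0.01)
  # degenerate at |r| = 1
  expect_equal(fisher_z_ci(1, 10)$low, 1)
  # monotone in n: smaller samples give wider intervals
  w <- sapply(c(5, 10, 50, 500), function(n) {
    ci <- fisher_z_ci(0.4, n); ci$high - ci$low
  })
  expect_true(all(diff(w) < 0))
})

test_that("zou_diff_ci behaves correctly and matches a step-by-step oracle", {
  eq <- zou_diff_ci(0.6, 0.6, 0.5, 18)
  expect_equal(eq$estimate, 0)
  expect_lt(eq$low, 0)
  expect_gt(eq$high, 0)
  # higher overlap correlation gives a narrower interval
  w0 <- with(zou_diff_ci(0.6, 0.3, 0, 18), high - low)
  w9 <- with(zou_diff_ci(0.6, 0.3, 0.9, 18), high - low)
  expect_lt(w9, w0)
  set.seed(7)
  for (i in 1:50) {
    repeat {
      r <- runif(3, -0.8, 0.8)
      det3 <- 1 + 2 * prod(r) - sum(r^2)
      if (det3 > 0.01) break
    }
    got <- zou_diff_ci(r[1], r[2], r[3], 18)
    want <- bf_zou(r[1], r[2], r[3], 18)
    expect_equal(c(got$low, got$high), want, tolerance = 1e-12)
  }
  # monotone in n
  wn <- sapply(c(6, 12, 60), function(n) {
    with(zou_diff_ci(0.5, 0.2, 0.4, n), high - low)
  })
  expect_true(all(diff(wn) < 0))
})

test_that("binom_test_exact equals pmf enumeration and closed forms", {
  expect_equal(binom_test_exact(5, 10), 1.0)
  expect_equal(binom_test_exact(0, 10), 2 * 2^-10)
  set.seed(11)
  for (i in 1:60) {
    n <- sample(1:20, 1)
    k <- sample(0:n, 1)
    expect_equal(binom_test_exact(k, n), bf_binom_p(k, n), tolerance = 1e-12)
  }
})

test_that("theil_sen is exact on lines and robust to one gross outlier", {
  x <- 1:10
  ts <- theil_sen(x, 0.5 * x + 1)
  expect_equal(ts$slope, 0.5)
  expect_equal(ts$intercept, 1)
  expect_equal(theil_sen(x, rep(3, 10))$slope, 0)
  # one wild outlier among 9 points leaves the slope untouched
  x9 <- 1:9
  y9 <- 2 * x9 + 1
  y9[5] <- 100
  expect_equal(theil_sen(x9, y9)$slope, bf_theil_sen(x9, y9)$slope)
  expect_equal(theil_sen(x9, y9)$slope, 2)
  # slope invariant under constant shift of y
  set.seed(3)
  xr <- rnorm(8); yr <- rnorm(8)
  expect_equal(theil_sen(xr, yr)$slope, theil_sen(xr, yr + 5)$slope)
  expect_equal(theil_sen(xr, yr)$slope, bf_theil_sen(xr, yr)$slope)
  expect_error(theil_sen(rep(1, 4), 1:4), "identical")
})

test_that("passing_bablok recovers exact lines and is symmetric", {
  x <- c(1, 2, 3, 5, 8, 13)
  fit <- passing_bablok(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  set.seed(5)
  xr <- rnorm(15); yr <- 1.4 * xr + rnorm(15, sd = 0.3)
  f1 <- passing_bablok(xr, yr)
  f2 <- passing_bablok(yr, xr)
  expect_equal(f1$slope, 1 / f2$slope, tolerance = 1e-10)
  # scale equivariance on co-monotone data (all pairwise slopes positive, so
  # the -1 discard rule and the K offset are inert under rescaling)
  xc <- sort(rnorm(15)); yc <- 1.4 * xc + cumsum(abs(rnorm(15, sd = 0.1)))
  fc <- passing_bablok(xc, yc)
  fk <- passing_bablok(xc / 2, yc)
  expect_equal(fk$slope, fc$slope * 2, tolerance = 1e-10)
  f3 <- passing_bablok(xc, 3 * yc)
  expect_equal(f3$slope, 3 * fc$slope, tolerance = 1e-10)
  expect_true(f1$slope_ci$low <= f1$slope && f1$slope <= f1$slope_ci$high)
  expect_lte(f1$n_slopes, f1$n_pairs * (f1$n_pairs - 1) / 2)
})

test_that("passing_bablok agrees with the brute-force oracle", {
  set.seed(9)
  for (i in 1:30) {
    x <- round(rnorm(12), 2)
    y <- round(0.8 * x + rnorm(12, sd = 0.5), 2)
    got <- passing_bablok(x, y)
    want <- bf_passing_bablok(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-12)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-12)
    expect_equal(got$slope_ci$low, want$lo, tolerance = 1e-12)
    expect_equal(got$slope_ci$high, want$hi, tolerance = 1e-12)
    expect_equal(got$n_slopes, want$N)
  }
})

test_that("ols_fit matches normal equations and performs the joint test", {
  x <- 1:6
  exact <- suppressWarnings(ols_fit(x, x))  # lm warns on perfect fits
  expect_equal(exact$slope, 1)
  expect_equal(exact$r_squared, 1)
  expect_true(exact$inside)
  f2 <- suppressWarnings(ols_fit(x, 2 * x))
  expect_equal(f2$slope, 2)
  expect_false(f2$inside)
  # textbook normal-equations oracle
  set.seed(13)
  xr <- rnorm(20); yr <- 1 + 0.7 * xr + rnorm(20, sd = 0.4)
  fit <- ols_fit(xr, yr)
  b <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
  a <- mean(yr) - b * mean(xr)
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$intercept, a, tolerance = 1e-12)
  # joint test of the true generating parameters on noiseless data
  fit3 <- suppressWarnings(ols_fit(xr, 1 + 0.7 * xr, slope0 = 0.7,
                                   intercept0 = 1))
  expect_true(fit3$inside)
  expect_error(ols_fit(rep(2, 5), 1:5), "degenerate")
})
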