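test_that("robust_detrend removes linear trends exactly and is idempotent", {
  t <- seq(0, 100, by = 5)
  y <- 0.5 * t + 1
  d <- robust_detrend(t, y)
  expect_equal(d$residuals, rep(0, length(t)))
  expect_equal(d$slope, 0.5)
  dc <- robust_detrend(t, rep(2, length(t)))
  expect_equal(dc$slope, 0)
  expect_equal(dc$residuals, rep(0, length(t)))
  # idempotence: detrending residuals changes nothing
  set.seed(6)
  y2 <- 0.2 * t + rnorm(length(t))
  d1 <- robust_detrend(t, y2)
  d2 <- robust_detrend(t, d1$residuals)
  expect_equal(d2$slope, 0, tolerance = 1e-10)
  expect_equal(d2$residuals, d1$residuals, tolerance = 1e-10)
  # outlier-resistant: matches brute force with a gross outlier
  y3 <- 2 * t[1:9] + 1; y3[4] <- 500
  expect_equal(robust_detrend(t[1:9], y3)$slope,
               bf_theil_sen(t[1:9], y3)$slope)
})

make_pairs <- function(T_d, o_d, t_g = seq_along(T_d)) {
  structure(list(t_g = t_g, T_d = T_d, o_d = o_d,
                 trend_T = list(slope = 0, intercept = 0),
                 trend_o = list(slope = 0, intercept = 0)),
            class = "detrended_pairs")
}

test_that("per-trial correlations use average-rank Spearman", {
  pl <- list(make_pairs(c(1, 2, 3), c(2, 4, 9)),
             make_pairs(c(1, 2, 3), c(5, 4, 1)),
             make_pairs(c(1, 2, 3, 4), c(2, 2, 5, 4)),
             make_pairs(c(1, 2), c(1, 2)))
  ids <- data.frame(subject_id = c(1, 1, 2, 2), trial_id = 1:4)
  st <- per_trial_correlations(pl, ids = ids)
  expect_equal(st$rho[1], 1)
  expect_equal(st$rho[2], -1)
  expect_equal(st$rho[3], 3.5 / sqrt(22.5))  # hand-ranked tie case
  expect_false(st$used[4])  # below the 3-pair minimum
  expect_equal(st$n_pairs, c(3, 3, 4, 2))
})

test_that("sign tests reproduce the exact binomial p-values", {
  # 58 positive of 61 trials across 18 subjects, all subject medians positive
  rho <- c(rep(0.5, 58), rep(-0.2, 3))
  st <- data.frame(subject_id = rep(1:18, length.out = 61),
                   trial_id = 1:61, n_pairs = 10, rho = rho, used = TRUE)
  sg <- sign_tests(st)
  expect_equal(sg$k_trials, 58)
  expect_equal(signif(sg$p_trials, 2), 3.3e-14)
  expect_equal(sg$k_subjects, 18)
  expect_equal(signif(sg$p_subjects, 2), 7.6e-6)
  # symmetric center: 5 of 10
  st2 <- data.frame(subject_id = 1:10, trial_id = 1:10, n_pairs = 10,
                    rho = c(rep(1, 5), rep(-1, 5)), used = TRUE)
  expect_equal(sign_tests(st2)$p_trials, 1.0)
  # zero correlations count as non-positive
  st3 <- st2; st3$rho[1] <- 0
  expect_equal(sign_tests(st3)$k_trials, 4)
})

test_that("subject_pb_fit recovers lines, symmetry, and equivariance", {
  T_d <- c(-2, -1, -0.3, 0.4, 1.1, 2, 2.5, -1.7, 0.9, 1.4, -0.6, 0.1)
  fit <- subject_pb_fit(list(make_pairs(T_d, 2 * T_d)))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_false(fit$low_n)
  # symmetry/equivariance on co-monotone data with an odd slope count
  # (the even-count middle-pair average is only reciprocal up to its mean)
  set.seed(12)
  T15 <- sort(rnorm(15))
  o15 <- 0.8 * T15 + cumsum(abs(rnorm(15, sd = 0.05)))
  f1 <- subject_pb_fit(list(make_pairs(T15, o15)))
  f2 <- subject_pb_fit(list(make_pairs(o15, T15)))
  expect_equal(f1$slope, 1 / f2$slope, tolerance = 1e-10)
  fk <- subject_pb_fit(list(make_pairs(T15 / 3, o15)))
  expect_equal(fk$slope, 3 * f1$slope, tolerance = 1e-10)
  o_d <- 0.8 * T_d + rnorm(12, sd = 0.2)
  f5 <- subject_pb_fit(list(make_pairs(T_d[1:5], o_d[1:5])))
  expect_true(f5$low_n)
  expect_lte(f1$n_slopes, f1$n_pairs * (f1$n_pairs - 1) / 2)
})

test_that("glance_analysis ties the pieces together on simulated data", {
  recs <- small_subject_trials(n_trials = 3, noise_sd = 1,
                               targets = c(50, 30, 60, 0, 40, 70, 80))
  g <- glance_analysis(recs)
  expect_true(all(g$trial_stats$n_pairs > 3))
  expect_true(all(abs(g$trial_stats$rho[g$trial_stats$used]) <= 1))
  expect_equal(nrow(g$pb_fits), 1)
  expect_true(is.finite(g$signs$p_trials))
})
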