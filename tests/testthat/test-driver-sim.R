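test_that("preferred_headway implements both adaptation variants", {
  p <- driver_params(T0 = 1, c = 1)
  expect_equal(preferred_headway(p, 0.5), 1.5)
  expect_equal(preferred_headway(p, 0), 1)
  pr <- driver_params(variant = "baseline_relative", hoogendoorn_TH = 1,
                      hoogendoorn_md_scale = 1)
  expect_equal(preferred_headway(pr, 1), 2)
  # strictly increasing in the mean occlusion duration
  o <- seq(0, 5, by = 0.5)
  expect_true(all(diff(preferred_headway(p, o)) > 0))
  expect_true(all(diff(preferred_headway(pr, o)) > 0))
  expect_error(preferred_headway(p, -0.1), "non-negative")
})

test_that("next_occlusion_duration is the clipped linear glance law", {
  p <- driver_params(o_base = 2, beta = 1, o_min = 0.3, o_max = 10)
  expect_equal(next_occlusion_duration(p, 3, 2), 3)
  expect_equal(next_occlusion_duration(p, 2, 2), 2)
  p2 <- driver_params(o_base = 0.5, beta = 1, o_min = 0.3, o_max = 10)
  expect_equal(next_occlusion_duration(p2, 0.2, 2), 0.3)
})

test_that("belief dead-reckons at last perceived speed", {
  b <- update_belief(list(x = 100, v = 10), 0.5)
  expect_equal(b$x, 105)
  expect_equal(b$v, 10)
  # a leader decelerating during occlusion ends up behind the belief
  v <- 10; x <- 100
  for (i in 1:50) { v <- max(v - 2 * 0.1, 0); x <- x + v * 0.1 }
  b5 <- update_belief(list(x = 100, v = 10), 5)
  expect_gt(b5$x, x)  # believed gap exceeds the true gap
})

test_that("follower control has the required equilibrium and signs", {
  p <- driver_params(noise_sd = 0)
  eq <- follower_accel(list(x = 100 + 1.5 * 13.89 + p$vehicle_length,
                            v = 13.89), 100, 13.89, 1.5, p)
  expect_equal(eq, 0)
  short <- follower_accel(list(x = 100 + 5 + p$vehicle_length, v = 13.89),
                          100, 13.89, 1.5, p)
  expect_lt(short, 0)
})

test_that("closed-loop headway converges to the preferred value", {
  p <- driver_params(noise_sd = 0)
  sched <- make_leader_schedule(1800, targets = 50)
  r <- simulate_trial("unoccluded", params = p, schedule = sched, seed = 5,
                      trial_length = 1e9, max_time = 120)
  Tser <- time_headway(r$x_lead, r$x_fol, r$v_fol,
                       vehicle_length = p$vehicle_length)
  late <- r$t > 60
  expect_lt(max(abs(Tser[late] - p$T0) / p$T0), 0.01)
})

test_that("simulated trials satisfy their structural invariants", {
  r <- simulate_trial("occluded", seed = 42)
  expect_false(r$crashed)
  expect_gte(r$x_fol[length(r$x_fol)], r$trial_length)
  expect_true(all(diff(r$x_lead) >= 0))
  expect_true(all(diff(r$x_fol) >= 0))
  expect_true(all(r$v_lead >= 0))
  expect_true(all(r$v_fol >= 0))
  expect_true(all(diff(r$glance_onsets) >=
                    r$params$glance_dur + r$params$o_min - 1e-9))
  # occlusion durations recoverable exactly from onsets
  rec_o <- diff(r$glance_onsets) - r$params$glance_dur
  expect_equal(rec_o, r$sched_o[-length(r$sched_o)], tolerance = 1e-9)
  ru <- simulate_trial("unoccluded", seed = 42)
  expect_length(ru$glance_onsets, 0)
  expect_error(simulate_trial("occluded", dt = 0), "positive")
  expect_error(simulate_trial("occluded", trial_length = -1), "positive")
})

test_that("a blind short-headway driver crashes into a braking leader", {
  p <- driver_params(T0 = 0.3, o_base = 10, o_min = 10, o_max = 10,
                     noise_sd = 0)
  sched <- make_leader_schedule(1800, targets = c(70, 0, 0, 0),
                                accel_bounds = c(-4, 3))
  r <- simulate_trial("occluded", params = p, schedule = sched, seed = 3)
  expect_true(r$crashed)
  n <- length(r$t)
  gap <- r$x_lead[n] - r$x_fol[n] - p$vehicle_length
  expect_lte(gap, 0)
})

test_that("identical seeds reproduce trials exactly", {
  a <- simulate_trial("occluded", seed = 77)
  b <- simulate_trial("occluded", seed = 77)
  expect_identical(a$x_fol, b$x_fol)
  expect_identical(a$v_lead, b$v_lead)
  expect_identical(a$glance_onsets, b$glance_onsets)
  d <- simulate_trial("occluded", seed = 78)
  expect_false(identical(a$x_fol, d$x_fol))
})

test_that("compiled integrator matches the plain-R reference step for step", {
  p <- driver_params(noise_sd = 0, glance_noise_sd = 0)
  for (cond in c("unoccluded", "occluded")) {
    sched <- make_leader_schedule(100, targets = c(50, 30, 60, 0, 40))
    got <- simulate_trial(cond, params = p, schedule = sched, seed = 1,
                          trial_length = 2000, max_time = 60)
    want <- bf_trial(cond == "occluded", p, sched, max_time = 60)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$x_fol, want$x_fol, tolerance = 1e-8)
    expect_equal(got$v_fol, want$v_fol, tolerance = 1e-8)
    expect_equal(got$x_lead, want$x_lead, tolerance = 1e-8)
    expect_equal(got$glance_onsets, want$glance_onsets, tolerance = 1e-9)
    expect_equal(got$sched_o, want$sched_o, tolerance = 1e-9)
  }
})

test_that("raising the headway-adaptation slope raises occluded headway", {
  # T0 = 2.5 s so the non-adapting (c = 0) driver survives blind driving
  # often enough to give usable pairs
  wins <- 0; valid <- 0
  for (i in 1:20) {
    sched <- withr::with_seed(300 + i, make_leader_schedule(1800))
    m <- sapply(c(0, 1), function(cc) {
      p <- driver_params(T0 = 2.5, c = cc)
      r <- simulate_trial("occluded", params = p, schedule = sched,
                          seed = 300 + i)
      ser <- trim_and_filter(r)
      if (r$crashed || length(ser$T) == 0) NA_real_ else mean(ser$T)
    })
    if (anyNA(m)) next  # a crashed member leaves the pair uninformative
    valid <- valid + 1
    if (m[2] > m[1]) wins <- wins + 1
  }
  expect_gte(valid, 10)
  expect_gte(wins / valid, 0.90)
})

test_that("simulate_experiment produces the full factorial design", {
  pop <- population_spec(n_subjects = 2, trials_per_condition = 1,
                         master_seed = 5)
  ex <- simulate_experiment(pop)
  expect_length(ex, 4)
  expect_setequal(vapply(ex, function(r) r$condition, character(1)),
                  c("occluded", "unoccluded"))
  # zero heterogeneity: both subjects share identical parameters
  pop0 <- population_spec(n_subjects = 2, trials_per_condition = 1,
                          T0_sdlog = 0, o_base_sdlog = 0,
                          pref_jitter_sdlog = 0, master_seed = 5)
  ex0 <- simulate_experiment(pop0)
  subj <- attr(ex0, "subjects")
  expect_equal(subj$T0[1], subj$T0[2])
  expect_equal(subj$o_base[1], subj$o_base[2])
  # same master seed -> identical datasets
  ex2 <- simulate_experiment(pop)
  expect_identical(ex[[3]]$x_fol, ex2[[3]]$x_fol)
  expect_identical(ex[[2]]$glance_onsets, ex2[[2]]$glance_onsets)
  expect_error(population_spec(trials_per_condition = 0))
})
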