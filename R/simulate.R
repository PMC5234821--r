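#' Preferred time headway under visual distraction
#'
#' Baseline-independent variant: `T' = T0 + c * o_mean`, a headway increase
#' directly proportional to the mean occlusion duration. Baseline-relative
#' variant: `T' = TH' * (m_d^3 + 1)` with task-difficulty index
#' `m_d = o_mean / hoogendoorn_md_scale`, so the increase scales with the
#' undistracted headway TH'.
#'
#' @param params A [driver_params()] object.
#' @param o_mean Mean occlusion duration, seconds (0 for unoccluded driving).
#' @return Preferred time headway, seconds.
#' @export
preferred_headway <- function(params, o_mean) {
  stopifnot(inherits(params, "driver_params"), is.numeric(o_mean))
  if (any(o_mean < 0)) stop("o_mean must be non-negative")
  if (params$variant == "baseline_independent") {
    params$T0 + params$c * o_mean
  } else {
    md <- o_mean / params$hoogendoorn_md_scale
    params$hoogendoorn_TH * (md^3 + 1)
  }
}

#' Next self-chosen occlusion duration
#'
#' The glance scheduler: when the current headway exceeds the preferred one
#' the driver affords a longer eyes-off interval, and vice versa,
#' `o = clip(o_base + beta * (T_now - T_pref), o_min, o_max)`. Equals
#' `o_base` exactly when the headway is at preference.
#'
#' @param params A [driver_params()] object.
#' @param T_now Current (perceived) time headway, seconds.
#' @param T_pref Preferred time headway, seconds.
#' @return Occlusion duration, seconds, within the clip bounds.
#' @export
next_occlusion_duration <- function(params, T_now, T_pref) {
  stopifnot(inherits(params, "driver_params"), is.finite(T_now),
            is.finite(T_pref))
  pmin(pmax(params$o_base + params$beta * (T_now - T_pref),
            params$o_min), params$o_max)
}

#' Dead-reckoned belief about the leader
#'
#' During occlusion the follower extrapolates the leader at its last
#' perceived speed; whenever vision is available the belief is the true
#' state.
#'
#' @param belief List with `x` (m) and `v` (m/s) at the last perception.
#' @param dt Time elapsed since the belief was last updated, seconds.
#' @return Updated belief list.
#' @export
update_belief <- function(belief, dt) {
  stopifnot(is.list(belief), is.numeric(belief$x), is.numeric(belief$v),
            dt >= 0)
  list(x = belief$x + belief$v * dt, v = belief$v)
}

#' Follower acceleration from believed leader state
#'
#' Linear speed-plus-gap tracker:
#' `a = clip(k_speed * (v_lead_hat - v) + g + eps)` where
#' `g = min(k_gap * (gap_hat - T_pref * v), gap_accel_cap)` and
#' `eps ~ Normal(0, noise_sd)`. The cap bounds the eagerness with which large
#' gaps are closed (braking is limited only by `accel_bounds`); near
#' equilibrium it is inactive, so with zero noise and a true belief,
#' `gap = T_pref * v`, `v = v_lead` is an equilibrium.
#'
#' @param belief List with believed leader position `x` (m) and speed `v`
#'   (m/s).
#' @param x_fol,v_fol Follower position (m) and speed (m/s, >= 0).
#' @param T_pref Preferred time headway, seconds.
#' @param params A [driver_params()] object.
#' @return Acceleration, m/s^2.
#' @export
follower_accel <- function(belief, x_fol, v_fol, T_pref, params) {
  stopifnot(v_fol >= 0)
  gap_hat <- belief$x - x_fol - params$vehicle_length
  gterm <- min(params$k_gap * (gap_hat - T_pref * v_fol),
               params$gap_accel_cap)
  a <- params$k_speed * (belief$v - v_fol) + gterm
  if (params$noise_sd > 0) a <- a + stats::rnorm(1, 0, params$noise_sd)
  min(max(a, params$accel_bounds[1]), params$accel_bounds[2])
}

#' Simulate one car-following trial
#'
#' Fixed-step explicit Euler integration (default dt = 0.01 s) of a
#' leader-follower pair until the follower has progressed `trial_length`
#' metres, a crash occurs (bumper gap <= 0), or `max_time` is exceeded. In
#' the occluded condition the follower perceives the leader only during
#' self-requested glances of `glance_dur` seconds; at every glance onset the
#' following occlusion duration is scheduled from the perceived headway via
#' [next_occlusion_duration()], and the preferred headway tracks the running
#' geometric mean of realized occlusion durations via [preferred_headway()].
#' Bit-reproducible given `seed`.
#'
#' @param condition `"occluded"` or `"unoccluded"`.
#' @param params A [driver_params()] object.
#' @param schedule A [make_leader_schedule()] object covering `max_time`.
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @param dt Integration step, seconds (default 0.01).
#' @param trial_length Trial distance, metres (default 2000).
#' @param max_time Hard time cap, seconds (default 1800).
#' @param subject_id,trial_id Identifiers stored in the record.
#' @param o_state Optional running occlusion-mean state carried across a
#'   subject's trials: list with `log_sum` and `n` (defaults to the
#'   o_base-initialized state).
#' @param init_gap_floor Minimum initial bumper gap, metres (guards the
#'   degenerate start when the first leader target is 0 km/h).
#' @param headway_cap Cap on the perceived headway fed to the glance
#'   scheduler, seconds.
#' @param headway_floor_speed Floor speed (m/s) used when converting the
#'   perceived gap to a headway for glance scheduling: at walking-pace or
#'   standstill the relevant eyes-off budget is the time to cover the gap at
#'   a modest resuming speed, not `gap / v -> infinity`.
#' @return A `trial_record`: list with `t`, `x_lead`, `v_lead`, `x_fol`,
#'   `v_fol` (series), `glance_onsets`, `sched_o` (scheduled occlusion
#'   durations), `crashed`, `condition`, `dt`, `trial_length`, identifiers,
#'   the updated `o_state`, and the `params` used.
#' @export
simulate_trial <- function(condition = c("occluded", "unoccluded"),
                           params = driver_params(),
                           schedule = NULL, seed = NULL, dt = 0.01,
                           trial_length = 2000, max_time = 1800,
                           subject_id = 1L, trial_id = 1L, o_state = NULL,
                           init_gap_floor = 5, headway_cap = 30,
                           headway_floor_speed = 5) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "driver_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- make_leader_schedule(max_time)
  if (is.null(o_state)) o_state <- list(log_sum = 0, n = 0L)
  if (dt <= 0) stop("dt must be positive")
  if (trial_length <= 0) stop("trial_length must be positive")
  if (schedule$duration < max_time) {
    stop("leader schedule shorter than max_time")
  }
  out <- sim_trial_cpp(
    occluded = condition == "occluded", dt = dt,
    trial_length = trial_length, max_time = max_time,
    segment_dur = schedule$segment_dur,
    targets_ms = schedule$target_speeds * KMH_TO_MS,
    l_gain = schedule$gain, l_amin = schedule$accel_bounds[1],
    l_amax = schedule$accel_bounds[2],
    T0 = params$T0, cslope = params$c, beta = params$beta,
    o_base = params$o_base, o_min = params$o_min, o_max = params$o_max,
    glance_dur = params$glance_dur, k_speed = params$k_speed,
    k_gap = params$k_gap, gap_accel_cap = params$gap_accel_cap,
    f_amin = params$accel_bounds[1],
    f_amax = params$accel_bounds[2], noise_sd = params$noise_sd,
    variant = if (params$variant == "baseline_independent") 0L else 1L,
    th_prime = params$hoogendoorn_TH,
    md_scale = params$hoogendoorn_md_scale,
    veh_len = params$vehicle_length, init_gap_floor = init_gap_floor,
    o_log_sum0 = o_state$log_sum, o_log_n0 = o_state$n,
    headway_cap = headway_cap, headway_floor_speed = headway_floor_speed,
    glance_noise_sd = params$glance_noise_sd)
  structure(list(subject_id = subject_id, trial_id = trial_id,
                 condition = condition,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 dt = dt, trial_length = trial_length,
                 t = out$t, x_lead = out$x_lead, v_lead = out$v_lead,
                 x_fol = out$x_fol, v_fol = out$v_fol,
                 glance_onsets = out$glance_onsets, sched_o = out$sched_o,
                 crashed = out$crashed,
                 o_state = list(log_sum = out$o_log_sum, n = out$o_log_n),
                 params = params),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject %s trial %s (%s)%s: %d samples, %d glances\n",
              x$subject_id, x$trial_id, x$condition,
              if (x$crashed) " CRASHED" else "",
              length(x$t), length(x$glance_onsets)))
  invisible(x)
}

# Draw per-subject driver parameters from the population distributions.
draw_subject_params <- function(pop, defaults) {
  T0 <- stats::rlnorm(1, pop$T0_meanlog, pop$T0_sdlog)
  o_base <- stats::rlnorm(1, pop$o_base_meanlog, pop$o_base_sdlog)
  cc <- stats::rlnorm(1, pop$c_meanlog, pop$c_sdlog)
  beta <- stats::rlnorm(1, pop$beta_meanlog, pop$beta_sdlog)
  p <- defaults
  p$T0 <- T0
  p$hoogendoorn_TH <- T0  # baseline-relative default headway shares T0's draw
  p$o_base <- max(o_base, p$o_min)
  p$c <- cc
  p$beta <- beta
  p
}

#' Simulate a full occlusion experiment
#'
#' Draws per-subject parameters from the population distributions, then runs
#' `trials_per_condition` occluded and unoccluded trials per subject (the
#' study design is 18 subjects with 4 trials of each task, 144 trials in
#' all). Per-subject and per-trial seeds are derived reproducibly from
#' `pop$master_seed`. Within each occluded trial the preferred headway
#' adapts to the running geometric mean of that trial's realized occlusion
#' durations, restarted at `o_base` at every trial start.
#'
#' @param pop A [population_spec()] object.
#' @param defaults A [driver_params()] object providing non-heterogeneous
#'   parameters (gains, bounds, noise, variant).
#' @param dt,trial_length,max_time Passed to [simulate_trial()].
#' @return List of `trial_record`s (class `occlusion_experiment`), with the
#'   drawn per-subject parameter table in attribute `subjects`.
#' @export
simulate_experiment <- function(pop = population_spec(),
                                defaults = driver_params(),
                                dt = 0.01, trial_length = 2000,
                                max_time = 1800) {
  stopifnot(inherits(pop, "population_spec"),
            inherits(defaults, "driver_params"))
  set.seed(pop$master_seed)
  n_trials <- pop$n_subjects * pop$trials_per_condition * 2L
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  records <- vector("list", n_trials)
  subjects <- vector("list", pop$n_subjects)
  k <- 0L
  for (s in seq_len(pop$n_subjects)) {
    p <- draw_subject_params(pop, defaults)
    subjects[[s]] <- data.frame(subject_id = s, T0 = p$T0,
                                o_base = p$o_base, c = p$c, beta = p$beta)
    for (tr in seq_len(pop$trials_per_condition)) {
      for (cond in c("occluded", "unoccluded")) {
        k <- k + 1L
        # slow between-trial drift in the preference parameters
        ptrial <- p
        if (pop$pref_jitter_sdlog > 0) {
          jit <- stats::rlnorm(2, 0, pop$pref_jitter_sdlog)
          ptrial$T0 <- p$T0 * jit[1]
          ptrial$hoogendoorn_TH <- p$hoogendoorn_TH * jit[1]
          ptrial$o_base <- max(p$o_base * jit[2], p$o_min)
        }
        sched <- make_leader_schedule(max_time)
        rec <- simulate_trial(cond, params = ptrial, schedule = sched,
                              seed = trial_seeds[k], dt = dt,
                              trial_length = trial_length,
                              max_time = max_time, subject_id = s,
                              trial_id = tr)
        records[[k]] <- rec
      }
    }
  }
  structure(records, subjects = do.call(rbind, subjects),
            master_seed = pop$master_seed, class = "occlusion_experiment")
}

#' @export
print.occlusion_experiment <- function(x, ...) {
  n_crash <- sum(vapply(x, function(r) r$crashed, logical(1)))
  cat(sprintf("<occlusion_experiment> %d trials (%d crashed), %d subjects\n",
              length(x), n_crash, nrow(attr(x, "subjects"))))
  invisible(x)
}
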