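# Shared fixtures built in code.

# A hand-built trial record with a controllable sample grid, for exercising
# the trim/filter logic without running the simulator.
fake_record <- function(odometer, v_fol, gap = 20, condition = "unoccluded",
                        trial_length = 2000, dt = 0.1,
                        glance_onsets = numeric(0),
                        params = driver_params(), crashed = FALSE) {
  n <- length(odometer)
  v_fol <- rep_len(v_fol, n)
  gap <- rep_len(gap, n)
  x_fol <- odometer
  structure(list(subject_id = 1L, trial_id = 1L, condition = condition,
                 seed = NA_integer_, dt = dt, trial_length = trial_length,
                 x_start = 0,
                 t = seq(0, by = dt, length.out = n),
                 x_lead = x_fol + gap + params$vehicle_length,
                 v_lead = v_fol, x_fol = x_fol, v_fol = v_fol,
                 glance_onsets = glance_onsets,
                 sched_o = if (length(glance_onsets) >= 2L)
                   diff(glance_onsets) - params$glance_dur else numeric(0),
                 crashed = crashed, o_state = NULL, params = params),
            class = "trial_record")
}

# A small simulated experiment: one subject, constant-speed leader,
# optionally noise-free. Returns the trial records.
small_subject_trials <- function(n_trials = 4, noise_sd = 0, seed0 = 100,
                                 targets = 50, params = NULL) {
  p <- params %||% driver_params(noise_sd = noise_sd,
                                 glance_noise_sd = if (noise_sd == 0) 0
                                                   else 0.1)
  sched <- make_leader_schedule(1800, targets = targets)
  recs <- list()
  for (tr in seq_len(n_trials)) {
    for (cond in c("occluded", "unoccluded")) {
      rec <- simulate_trial(cond, params = p, schedule = sched,
                            seed = seed0 + tr, subject_id = 1, trial_id = tr)
      recs <- c(recs, list(rec))
    }
  }
  recs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
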