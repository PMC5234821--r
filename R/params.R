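#' Driver model parameters
#'
#' Generative parameters for one simulated driver. The adaptation laws are
#' `T' = T0 + c * o_mean` (baseline-independent preferred headway) or the
#' baseline-relative Hoogendoorn-style variant `T' = TH' * (m_d^3 + 1)`, and
#' the glance scheduler `o = clip(o_base + beta * (T - T'), o_min, o_max)`.
#'
#' @param T0 Preferred unoccluded time headway, seconds. One second is a
#'   reasonable population-level first approximation.
#' @param c Headway increase per unit of mean occlusion duration
#'   (dimensionless); around 1 corresponds to one-to-one adaptation.
#' @param beta Glance-adaptation gain (dimensionless), typically around 1.
#' @param o_base Preferred occlusion duration o', seconds.
#' @param o_min,o_max Clip bounds on scheduled occlusion durations, seconds.
#' @param glance_dur Glance duration, seconds (default 0.3).
#' @param k_speed,k_gap Follower control gains on relative speed (1/s) and on
#'   gap error (1/s^2).
#' @param gap_accel_cap Cap on the positive (closing) contribution of the gap
#'   term, m/s^2; bounds the speed at which large gaps are closed so approach
#'   behaviour stays unaggressive. The braking side is limited only by
#'   `accel_bounds`.
#' @param accel_bounds Follower acceleration bounds, m/s^2, `c(min, max)` with
#'   min < 0 < max.
#' @param noise_sd Standard deviation of the per-step acceleration noise,
#'   m/s^2.
#' @param glance_noise_sd Standard deviation (seconds) of the noise added to
#'   each scheduled occlusion duration before clipping: drivers do not time
#'   their eyes-off intervals deterministically, and this scatter is what
#'   keeps the within-trial headway/occlusion correlation well below 1.
#' @param variant `"baseline_independent"` or `"baseline_relative"`.
#' @param hoogendoorn_TH Default time headway TH' for the baseline-relative
#'   variant, seconds.
#' @param hoogendoorn_md_scale Scale mapping mean occlusion duration to the
#'   task-difficulty index: `m_d = o_mean / hoogendoorn_md_scale` (seconds).
#' @param vehicle_length Vehicle length subtracted to obtain bumper gaps, m.
#' @return An object of class `driver_params`.
#' @export
driver_params <- function(T0 = 1.0, c = 1.0, beta = 1.0, o_base = 2.0,
                          o_min = 0.3, o_max = 10, glance_dur = 0.3,
                          k_speed = 2.5, k_gap = 0.6, gap_accel_cap = 6,
                          accel_bounds = c(-3, 3), noise_sd = 1.0,
                          glance_noise_sd = 0.1,
                          variant = c("baseline_independent",
                                      "baseline_relative"),
                          hoogendoorn_TH = 1.0, hoogendoorn_md_scale = 1.0,
                          vehicle_length = 4) {
  variant <- match.arg(variant)
  stopifnot(T0 > 0, is.finite(c), is.finite(beta), o_min > 0,
            o_min <= o_base, o_base <= o_max, glance_dur > 0,
            length(accel_bounds) == 2L,
            accel_bounds[1] < 0, accel_bounds[2] > 0,
            noise_sd >= 0, glance_noise_sd >= 0, hoogendoorn_TH > 0,
            hoogendoorn_md_scale > 0, vehicle_length >= 0, gap_accel_cap > 0)
  structure(list(T0 = T0, c = c, beta = beta, o_base = o_base,
                 o_min = o_min, o_max = o_max, glance_dur = glance_dur,
                 k_speed = k_speed, k_gap = k_gap,
                 gap_accel_cap = gap_accel_cap,
                 accel_bounds = as.numeric(accel_bounds),
                 noise_sd = noise_sd, glance_noise_sd = glance_noise_sd,
                 variant = variant,
                 hoogendoorn_TH = hoogendoorn_TH,
                 hoogendoorn_md_scale = hoogendoorn_md_scale,
                 vehicle_length = vehicle_length),
            class = "driver_params")
}

#' @export
print.driver_params <- function(x, ...) {
  cat("<driver_params>", x$variant, "\n")
  cat(sprintf("  T0 = %.3g s, c = %.3g, beta = %.3g, o' = %.3g s (clip %.3g-%.3g s)\n",
              x$T0, x$c, x$beta, x$o_base, x$o_min, x$o_max))
  cat(sprintf("  gains k_speed = %.3g /s, k_gap = %.3g /s^2, noise sd = %.3g m/s^2\n",
              x$k_speed, x$k_gap, x$noise_sd))
  invisible(x)
}

#' Population specification for a simulated experiment
#'
#' Between-subject heterogeneity is log-normal on the preference parameters:
#' `T0` (and the baseline-relative `TH'`) and `o_base` vary across subjects
#' while the adaptation gains `c` and `beta` are shared, mirroring the study
#' design of idiosyncratic headway/glance trade-offs around common adaptation
#' laws.
#'
#' @param n_subjects Number of subjects (default 18).
#' @param trials_per_condition Trials per subject in each of the occluded and
#'   unoccluded conditions (default 4).
#' @param T0_meanlog,T0_sdlog Log-scale location/scale of per-subject T0
#'   (defaults: median 1 s, sdlog 0.35).
#' @param o_base_meanlog,o_base_sdlog Log-scale location/scale of per-subject
#'   preferred occlusion duration (defaults: median 2 s, sdlog 0.45).
#' @param c_meanlog,c_sdlog Log-scale location/scale of the headway slope c
#'   (defaults: median 1, sdlog 0.18; per-subject variation in how strongly
#'   headway responds to distraction).
#' @param beta_meanlog,beta_sdlog Log-scale location/scale of the glance gain
#'   beta (defaults: median 1, sdlog 0.18; per-subject variation in glance
#'   adaptation, visible as the spread of per-subject symmetric-regression
#'   slopes).
#' @param pref_jitter_sdlog Log-scale sd of per-trial multiplicative jitter
#'   on the preference parameters T0 and o_base, reflecting slow
#'   within-subject drift in preferred headway and glance interval between
#'   trials (default 0.15; 0 disables).
#' @param master_seed Integer seed from which all subject/trial seeds derive.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 18, trials_per_condition = 4,
                            T0_meanlog = log(1.0), T0_sdlog = 0.35,
                            o_base_meanlog = log(2.0), o_base_sdlog = 0.45,
                            c_meanlog = log(1.0), c_sdlog = 0.18,
                            beta_meanlog = log(1.0), beta_sdlog = 0.18,
                            pref_jitter_sdlog = 0.15,
                            master_seed = 1L) {
  stopifnot(n_subjects >= 1, trials_per_condition >= 1,
            T0_sdlog >= 0, o_base_sdlog >= 0, c_sdlog >= 0, beta_sdlog >= 0,
            pref_jitter_sdlog >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 T0_meanlog = T0_meanlog, T0_sdlog = T0_sdlog,
                 o_base_meanlog = o_base_meanlog, o_base_sdlog = o_base_sdlog,
                 c_meanlog = c_meanlog, c_sdlog = c_sdlog,
                 beta_meanlog = beta_meanlog, beta_sdlog = beta_sdlog,
                 pref_jitter_sdlog = pref_jitter_sdlog,
                 master_seed = as.integer(master_seed)),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %d subjects x %d+%d trials, master seed %d\n",
              x$n_subjects, x$trials_per_condition, x$trials_per_condition,
              x$master_seed))
  invisible(x)
}
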