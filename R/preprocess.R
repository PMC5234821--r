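#' Instantaneous time headway
#'
#' Bumper-to-bumper gap divided by the follower's speed,
#' `(x_lead - x_fol - vehicle_length) / v_fol`, seconds. Samples with very
#' low speed are excluded downstream (the 1.0 m/s filter) rather than here.
#'
#' @param x_lead,x_fol Leader and follower positions, metres.
#' @param v_fol Follower speed, m/s (> 0 for a defined headway).
#' @param vehicle_length Vehicle length, metres (default 4).
#' @return Time headway, seconds (vectorised; NA where `v_fol <= 0`).
#' @export
time_headway <- function(x_lead, x_fol, v_fol, vehicle_length = 4) {
  th <- (x_lead - x_fol - vehicle_length) / v_fol
  th[v_fol <= 0] <- NA_real_
  th
}

#' Trim and filter a trial into its analysable headway series
#'
#' Retains exactly the samples whose follower odometer lies in
#' `[300, trial_length - 300]` metres (dropping the standing start and the
#' end-of-trial coasting) and whose ground speed is at least 1.0 m/s
#' (preventing extreme headway values); headway is computed per
#' [time_headway()].
#'
#' @param record A `trial_record`.
#' @param trim Metres trimmed from each end (default 300).
#' @param min_speed Minimum retained ground speed, m/s (default 1.0).
#' @return A `headway_series`: list with `t`, `odometer`, `T`, `v_fol`, plus
#'   trial metadata. Zero-length series are returned (not an error) so
#'   callers can drop and log the trial.
#' @export
trim_and_filter <- function(record, trim = 300, min_speed = 1.0) {
  stopifnot(inherits(record, "trial_record"))
  origin <- record$x_start %||% record$x_fol[1]
  odo <- record$x_fol - origin
  keep <- odo >= trim & odo <= record$trial_length - trim &
    record$v_fol >= min_speed
  th <- time_headway(record$x_lead[keep], record$x_fol[keep],
                     record$v_fol[keep],
                     vehicle_length = record$params$vehicle_length)
  structure(list(subject_id = record$subject_id,
                 trial_id = record$trial_id,
                 condition = record$condition,
                 t = record$t[keep], odometer = odo[keep], T = th,
                 v_fol = record$v_fol[keep],
                 dt = record$dt, glance_dur = record$params$glance_dur),
            class = "headway_series")
}

#' Geometric mean
#'
#' `exp(mean(log(x)))` for strictly positive input; the aggregate used for
#' both time headways and occlusion durations.
#'
#' @param xs Positive numeric vector (non-empty).
#' @return The geometric mean.
#' @export
geometric_mean <- function(xs) {
  if (length(xs) == 0L) stop("empty input")
  if (anyNA(xs) || any(xs <= 0)) stop("all values must be positive")
  exp(mean(log(xs)))
}

#' Pair glance onsets with headway and the following occlusion duration
#'
#' For each glance onset except the last, the following occlusion duration is
#' `next_onset - (onset + glance_dur)` (the eyes-off interval after the
#' glance, excluding the glance itself) and the instantaneous headway is
#' linearly interpolated from the filtered series at the onset. Onsets
#' outside the trimmed window, or whose neighbouring headway samples were
#' filtered out, are dropped.
#'
#' @param record An occluded `trial_record`.
#' @param series Its [trim_and_filter()] output.
#' @return A data.frame with columns `t_g`, `T_at_onset`, `o_next`, ordered
#'   by `t_g` (possibly zero rows).
#' @export
glance_onset_samples <- function(record, series = trim_and_filter(record)) {
  stopifnot(inherits(record, "trial_record"))
  if (record$condition != "occluded") {
    stop("glance_onset_samples requires an occluded trial")
  }
  on <- record$glance_onsets
  if (length(on) < 2L) {
    return(data.frame(t_g = numeric(0), T_at_onset = numeric(0),
                      o_next = numeric(0)))
  }
  o_next <- diff(on) - record$params$glance_dur
  t_g <- on[-length(on)]
  if (length(series$t) == 0L) {
    return(data.frame(t_g = numeric(0), T_at_onset = numeric(0),
                      o_next = numeric(0)))
  }
  # an onset is usable only if a retained sample lies within one step on each
  # side (otherwise the headway there was trimmed or speed-filtered away)
  lo_idx <- findInterval(t_g, series$t)
  tol <- record$dt * 1.5
  ok <- lo_idx >= 1L & lo_idx < length(series$t)
  ok[ok] <- (t_g[ok] - series$t[lo_idx[ok]]) <= tol &
    (series$t[lo_idx[ok] + 1L] - t_g[ok]) <= tol
  exact <- abs(t_g - series$t[pmax(lo_idx, 1L)]) < 1e-9
  ok <- ok | (lo_idx >= 1L & lo_idx <= length(series$t) & exact)
  t_g <- t_g[ok]
  o_next <- o_next[ok]
  if (length(t_g) == 0L) {
    return(data.frame(t_g = numeric(0), T_at_onset = numeric(0),
                      o_next = numeric(0)))
  }
  T_at <- stats::approx(series$t, series$T, xout = t_g, rule = 1)$y
  keep <- !is.na(T_at)
  data.frame(t_g = t_g[keep], T_at_onset = T_at[keep], o_next = o_next[keep])
}

#' Per-subject aggregates
#'
#' Pools filtered headway samples across a subject's non-crashed trials of
#' each condition and takes geometric means: `T_hat_0` (unoccluded),
#' `T_hat_D` (occluded), and `o_hat_D`, the geometric mean of the pooled
#' occlusion durations from the glance-onset samples. Derived fields:
#' `delta_T = T_hat_D - T_hat_0` and `delta_rel = delta_T / T_hat_0`.
#'
#' @param records List of `trial_record`s for one subject.
#' @param include_crashed Keep crashed trials in the aggregates (default
#'   FALSE).
#' @param pool `"samples"` pools all samples across trials (default);
#'   `"trials"` averages per-trial geometric means.
#' @return A `subject_summary` list, or `NULL` (with a message) when a
#'   condition has no usable trial.
#' @export
subject_summary <- function(records, include_crashed = FALSE,
                            pool = c("samples", "trials")) {
  pool <- match.arg(pool)
  stopifnot(length(records) >= 1L)
  sid <- records[[1]]$subject_id
  if (!include_crashed) {
    records <- Filter(function(r) !r$crashed, records)
  }
  logs_T <- list(occluded = list(), unoccluded = list())
  o_logs <- list()
  n_used <- c(occluded = 0L, unoccluded = 0L)
  n_glances <- 0L
  for (r in records) {
    ser <- trim_and_filter(r)
    if (length(ser$T) == 0L) next
    logs_T[[r$condition]] <- c(logs_T[[r$condition]], list(log(ser$T)))
    n_used[r$condition] <- n_used[r$condition] + 1L
    if (r$condition == "occluded") {
      gs <- glance_onset_samples(r, ser)
      if (nrow(gs) > 0L) {
        o_logs <- c(o_logs, list(log(gs$o_next)))
        n_glances <- n_glances + nrow(gs)
      }
    }
  }
  if (n_used["occluded"] == 0L || n_used["unoccluded"] == 0L ||
      length(o_logs) == 0L) {
    message(sprintf("subject %s excluded: no usable trial in a condition", sid))
    return(NULL)
  }
  agg <- function(lst) {
    if (pool == "samples") exp(mean(unlist(lst)))
    else exp(mean(vapply(lst, mean, numeric(1))))
  }
  T_hat_0 <- agg(logs_T$unoccluded)
  T_hat_D <- agg(logs_T$occluded)
  o_hat_D <- agg(o_logs)
  structure(list(subject_id = sid, T_hat_0 = T_hat_0, T_hat_D = T_hat_D,
                 o_hat_D = o_hat_D, delta_T = T_hat_D - T_hat_0,
                 delta_rel = (T_hat_D - T_hat_0) / T_hat_0,
                 n_trials_used = n_used, n_glances = n_glances),
            class = "subject_summary")
}

#' Summarise every subject of an experiment
#'
#' @param records List of `trial_record`s (an `occlusion_experiment`).
#' @param ... Passed to [subject_summary()].
#' @return A data.frame with one row per retained subject: `subject_id`,
#'   `T_hat_0`, `T_hat_D`, `o_hat_D`, `delta_T`, `delta_rel`,
#'   `n_occluded`, `n_unoccluded`, `n_glances`.
#' @export
summarize_subjects <- function(records, ...) {
  ids <- vapply(records, function(r) r$subject_id, numeric(1))
  rows <- lapply(unique(ids), function(s) {
    ss <- subject_summary(records[ids == s], ...)
    if (is.null(ss)) return(NULL)
    data.frame(subject_id = ss$subject_id, T_hat_0 = ss$T_hat_0,
               T_hat_D = ss$T_hat_D, o_hat_D = ss$o_hat_D,
               delta_T = ss$delta_T, delta_rel = ss$delta_rel,
               n_occluded = ss$n_trials_used[["occluded"]],
               n_unoccluded = ss$n_trials_used[["unoccluded"]],
               n_glances = ss$n_glances)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
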