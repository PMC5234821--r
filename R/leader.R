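#' Leader target-speed set, km/h
#' @export
LEADER_TARGET_SET_KMH <- c(0, 30, 40, 50, 60, 70, 80)

#' Conversion factor km/h -> m/s (exactly 1/3.6)
#' @export
KMH_TO_MS <- 1 / 3.6

#' Randomised leader speed schedule
#'
#' A new target speed holds for each 10 s segment. Targets are drawn without
#' replacement from the 7-value set \{0, 30, 40, 50, 60, 70, 80\} km/h; when
#' the set is exhausted it is reshuffled, so every consecutive block of 7
#' segments is a full permutation of the set.
#'
#' @param duration Schedule length in seconds (> 0). The last segment may be
#'   shorter than 10 s.
#' @param gain Proportional control gain, 1/s. The default 1.2 brings even
#'   the largest target change (0 to 80 km/h) within 1 km/h of target inside
#'   one 10 s segment under the default bounds.
#' @param accel_bounds Leader acceleration bounds, m/s^2, `c(min, max)`; the
#'   defaults keep decelerations subtle.
#' @param segment_dur Segment length, seconds (default 10).
#' @param targets Optional fixed vector of target speeds (km/h), recycled to
#'   the schedule length, bypassing the random draw (useful for constructing
#'   constant-speed or scripted leader profiles).
#' @return An object of class `leader_schedule` with fields
#'   `segment_start_times` (s), `target_speeds` (km/h), `gain`,
#'   `accel_bounds`, `segment_dur`, `duration`.
#' @export
make_leader_schedule <- function(duration, gain = 1.2,
                                 accel_bounds = c(-2.5, 2.5),
                                 segment_dur = 10, targets = NULL) {
  stopifnot(is.numeric(duration), length(duration) == 1L)
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  stopifnot(gain > 0, length(accel_bounds) == 2L,
            accel_bounds[1] < 0, accel_bounds[2] > 0, segment_dur > 0)
  n_seg <- ceiling(duration / segment_dur)
  if (is.null(targets)) {
    n_block <- ceiling(n_seg / 7)
    targets <- unlist(lapply(seq_len(n_block), function(i) {
      sample(LEADER_TARGET_SET_KMH)
    }))[seq_len(n_seg)]
  } else {
    targets <- rep_len(as.numeric(targets), n_seg)
  }
  structure(list(segment_start_times = (seq_len(n_seg) - 1) * segment_dur,
                 target_speeds = targets,
                 gain = gain,
                 accel_bounds = as.numeric(accel_bounds),
                 segment_dur = segment_dur,
                 duration = duration),
            class = "leader_schedule")
}

#' @export
print.leader_schedule <- function(x, ...) {
  cat(sprintf("<leader_schedule> %d segments of %.3g s, gain %.3g /s\n",
              length(x$target_speeds), x$segment_dur, x$gain))
  invisible(x)
}

#' Leader acceleration under proportional speed control
#'
#' `a = clip(gain * (v_target - v), accel_bounds)`; zero at the target speed.
#'
#' @param v Current speed, m/s (>= 0).
#' @param v_target Target speed, m/s.
#' @param gain Proportional gain, 1/s.
#' @param accel_bounds `c(min, max)` acceleration limits, m/s^2.
#' @return Acceleration, m/s^2.
#' @export
leader_accel <- function(v, v_target, gain, accel_bounds) {
  stopifnot(all(v >= 0))
  pmin(pmax(gain * (v_target - v), accel_bounds[1]), accel_bounds[2])
}

# Target speed (m/s) in force at time t under a schedule.
schedule_target_ms <- function(schedule, t) {
  idx <- pmin(findInterval(t, schedule$segment_start_times),
              length(schedule$target_speeds))
  schedule$target_speeds[pmax(idx, 1L)] * KMH_TO_MS
}
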