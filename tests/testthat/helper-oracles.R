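# Brute-force reference implementations used as independent oracles.

# Average ranks computed by explicit sorting (no rank()).
bf_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

bf_spearman <- function(x, y) {
  rx <- bf_ranks(x)
  ry <- bf_ranks(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Exact two-sided binomial p by full pmf enumeration (small-probability sum).
bf_binom_p <- function(k, n, p0 = 0.5) {
  pmf <- vapply(0:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
                numeric(1))
  obs <- pmf[k + 1]
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

bf_theil_sen <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[i] != x[j]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  }
  b <- median(slopes)
  list(slope = b, intercept = median(y - b * x))
}

# Passing-Bablok step by step: pairwise slopes, drop -1, offset K, shifted
# median, rank-based CI.
bf_passing_bablok <- function(x, y, level = 0.95) {
  n <- length(x)
  s <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[i] != x[j]) {
      sij <- (y[j] - y[i]) / (x[j] - x[i])
      if (sij != -1) s <- c(s, sij)
    }
  }
  s <- sort(s)
  N <- length(s)
  K <- sum(s < -1)
  half <- N / 2
  b <- if (N %% 2 == 1) s[(N + 1) / 2 + K] else (s[half + K] + s[half + 1 + K]) / 2
  w <- qnorm((1 + level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - w) / 2)
  M2 <- N - M1 + 1
  list(slope = b, intercept = median(y - b * x),
       lo = s[M1 + K], hi = s[M2 + K], N = N, K = K)
}

# Zou's interval recomputed step by step (overlapping dependent case).
bf_zou <- function(r12, r13, r23, n, level = 0.95) {
  zci <- function(r) {
    hw <- qnorm((1 + level) / 2) / sqrt(n - 3)
    tanh(atanh(r) + c(-hw, hw))
  }
  c1 <- zci(r12); c2 <- zci(r13)
  rc <- ((r23 - 0.5 * r12 * r13) * (1 - r12^2 - r13^2 - r23^2) + r23^3) /
    ((1 - r12^2) * (1 - r13^2))
  d <- r12 - r13
  lo <- d - sqrt((r12 - c1[1])^2 + (c2[2] - r13)^2 -
                   2 * rc * (r12 - c1[1]) * (c2[2] - r13))
  hi <- d + sqrt((c1[2] - r12)^2 + (r13 - c2[1])^2 -
                   2 * rc * (c1[2] - r12) * (r13 - c2[1]))
  c(lo, hi)
}

# Plain-R mirror of the fixed-step trial integrator (noise-free only), used
# to validate the compiled loop on short runs.
bf_trial <- function(occluded, params, schedule, dt = 0.01,
                     trial_length = 2000, max_time = 60,
                     init_gap_floor = 5, headway_cap = 30,
                     headway_floor_speed = 5) {
  stopifnot(params$noise_sd == 0, params$glance_noise_sd == 0)
  pref <- function(o_mean) preferred_headway(params, o_mean)
  clip <- function(x, lo, hi) min(max(x, lo), hi)
  tg_ms <- schedule$target_speeds * KMH_TO_MS
  n_seg <- length(tg_ms)
  o_log_sum <- 0; o_log_n <- 0
  o_mean <- params$o_base
  T_pref <- if (occluded) pref(o_mean) else pref(0)
  v0 <- tg_ms[1]
  v_fol <- v0; x_fol <- 0
  gap0 <- max(T_pref * v0, init_gap_floor)
  x_lead <- gap0 + params$vehicle_length; v_lead <- v0
  bx <- x_lead; bv <- v_lead
  next_onset <- 0; glance_end <- -1
  o_min_q <- ceiling(params$o_min / dt - 1e-9) * dt
  ts <- xl <- vl <- xf <- vf <- numeric(0)
  onsets <- sched <- numeric(0)
  crashed <- FALSE
  i <- 0
  repeat {
    t <- i * dt
    if (t > max_time) break
    if (occluded && t >= next_onset - dt * 0.5) {
      onset <- next_onset
      bx <- x_lead; bv <- v_lead
      gap <- x_lead - x_fol - params$vehicle_length
      T_now <- clip(gap / max(v_fol, headway_floor_speed), 0, headway_cap)
      o <- clip(params$o_base + params$beta * (T_now - T_pref),
                params$o_min, params$o_max)
      o <- round(o / dt) * dt
      if (o < o_min_q) o <- o_min_q
      onsets <- c(onsets, onset); sched <- c(sched, o)
      o_log_sum <- o_log_sum + log(o); o_log_n <- o_log_n + 1
      o_mean <- exp(o_log_sum / o_log_n)
      T_pref <- pref(o_mean)
      glance_end <- onset + params$glance_dur
      next_onset <- onset + params$glance_dur + o
    }
    perceive <- !occluded || t < glance_end
    if (perceive) { bx <- x_lead; bv <- v_lead }
    ts <- c(ts, t); xl <- c(xl, x_lead); vl <- c(vl, v_lead)
    xf <- c(xf, x_fol); vf <- c(vf, v_fol)
    seg <- min(floor(t / schedule$segment_dur), n_seg - 1) + 1
    a_l <- clip(schedule$gain * (tg_ms[seg] - v_lead),
                schedule$accel_bounds[1], schedule$accel_bounds[2])
    bgap <- bx - x_fol - params$vehicle_length
    gterm <- min(params$k_gap * (bgap - T_pref * v_fol), params$gap_accel_cap)
    a_f <- clip(params$k_speed * (bv - v_fol) + gterm,
                params$accel_bounds[1], params$accel_bounds[2])
    v_lead <- max(v_lead + a_l * dt, 0)
    v_fol <- max(v_fol + a_f * dt, 0)
    x_lead <- x_lead + v_lead * dt
    x_fol <- x_fol + v_fol * dt
    if (!perceive) bx <- bx + bv * dt
    if (x_lead - x_fol - params$vehicle_length <= 0) {
      crashed <- TRUE
      ts <- c(ts, t + dt); xl <- c(xl, x_lead); vl <- c(vl, v_lead)
      xf <- c(xf, x_fol); vf <- c(vf, v_fol)
      break
    }
    if (x_fol >= trial_length) {
      ts <- c(ts, t + dt); xl <- c(xl, x_lead); vl <- c(vl, v_lead)
      xf <- c(xf, x_fol); vf <- c(vf, v_fol)
      break
    }
    i <- i + 1
  }
  list(t = ts, x_lead = xl, v_lead = vl, x_fol = xf, v_fol = vf,
       glance_onsets = onsets, sched_o = sched, crashed = crashed)
}
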