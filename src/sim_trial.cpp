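#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step (explicit Euler) integration of one car-following trial.
//
// The leader tracks a piecewise-constant target speed under proportional
// control. The follower acts on a *believed* leader state: refreshed to truth
// whenever vision is available (continuously in unoccluded trials, during
// 300 ms glance windows in occluded ones) and dead-reckoned at the last
// perceived speed otherwise. At each glance onset the next occlusion duration
// is scheduled from the currently perceived time headway:
//   o = clip(o_base + beta * (T_now - T_pref), o_min, o_max),
// quantized to the integration grid so scheduled durations are exactly
// recoverable from the recorded onset times. The preferred headway T_pref is
// re-evaluated from the running geometric mean of realized occlusion
// durations (baseline-independent: T0 + c * o_mean; baseline-relative:
// TH' * ((o_mean/md_scale)^3 + 1)).

static inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double pref_headway(int variant, double T0, double cslope,
                                  double th_prime, double md_scale,
                                  double o_mean) {
  if (variant == 0) return T0 + cslope * o_mean;
  double md = o_mean / md_scale;
  return th_prime * (md * md * md + 1.0);
}

// [[Rcpp::export]]
List sim_trial_cpp(bool occluded, double dt, double trial_length,
                   double max_time, double segment_dur,
                   NumericVector targets_ms, double l_gain, double l_amin,
                   double l_amax, double T0, double cslope, double beta,
                   double o_base, double o_min, double o_max,
                   double glance_dur, double k_speed, double k_gap,
                   double gap_accel_cap, double f_amin, double f_amax,
                   double noise_sd, int variant,
                   double th_prime, double md_scale, double veh_len,
                   double init_gap_floor, double o_log_sum0, int o_log_n0,
                   double headway_cap, double headway_floor_speed,
                   double glance_noise_sd) {
  if (dt <= 0) stop("dt must be positive");
  if (trial_length <= 0) stop("trial_length must be positive");

  const int max_steps = (int)(max_time / dt) + 2;
  std::vector<double> ts, xl, vl, xf, vf;
  ts.reserve(max_steps); xl.reserve(max_steps); vl.reserve(max_steps);
  xf.reserve(max_steps); vf.reserve(max_steps);
  std::vector<double> onsets, sched;

  double o_log_sum = o_log_sum0;
  int o_log_n = o_log_n0;
  double o_mean = (o_log_n > 0) ? std::exp(o_log_sum / o_log_n) : o_base;

  double T_pref = occluded
      ? pref_headway(variant, T0, cslope, th_prime, md_scale, o_mean)
      : pref_headway(variant, T0, cslope, th_prime, md_scale, 0.0);

  double v0 = targets_ms[0];
  double v_fol = v0, x_fol = 0.0;
  double gap0 = T_pref * v0;
  if (gap0 < init_gap_floor) gap0 = init_gap_floor;
  double x_lead = gap0 + veh_len, v_lead = v0;
  double bx = x_lead, bv = v_lead;  // believed leader state

  double next_onset = 0.0, glance_end = -1.0;
  bool crashed = false;
  const int n_seg = targets_ms.size();
  const double o_min_q = std::ceil(o_min / dt - 1e-9) * dt;

  int i = 0;
  for (;; ++i) {
    double t = i * dt;
    if (t > max_time) break;

    // glance onset event: schedule the next occlusion from perceived headway
    if (occluded && t >= next_onset - dt * 0.5) {
      double onset = next_onset;
      bx = x_lead; bv = v_lead;  // mask lifts: belief refreshed
      double gap = x_lead - x_fol - veh_len;
      // at low speed the headway fed to the glance scheduler reflects the
      // time to cover the gap at a modest resuming speed, not gap/v -> inf
      double T_now = gap / std::max(v_fol, headway_floor_speed);
      T_now = clip(T_now, 0.0, headway_cap);
      double o = o_base + beta * (T_now - T_pref);
      if (glance_noise_sd > 0) o += R::rnorm(0.0, glance_noise_sd);
      o = clip(o, o_min, o_max);
      o = std::round(o / dt) * dt;
      if (o < o_min_q) o = o_min_q;
      onsets.push_back(onset);
      sched.push_back(o);
      o_log_sum += std::log(o);
      o_log_n += 1;
      o_mean = std::exp(o_log_sum / o_log_n);
      T_pref = pref_headway(variant, T0, cslope, th_prime, md_scale, o_mean);
      glance_end = onset + glance_dur;
      next_onset = onset + glance_dur + o;
    }

    bool perceive = !occluded || (t < glance_end);
    if (perceive) { bx = x_lead; bv = v_lead; }

    ts.push_back(t); xl.push_back(x_lead); vl.push_back(v_lead);
    xf.push_back(x_fol); vf.push_back(v_fol);

    // accelerations from the state at t
    int seg = (int)(t / segment_dur);
    if (seg >= n_seg) seg = n_seg - 1;
    double a_l = clip(l_gain * (targets_ms[seg] - v_lead), l_amin, l_amax);
    double bgap = bx - x_fol - veh_len;
    // closing side of the gap term capped: unaggressive approach behaviour
    double gterm = k_gap * (bgap - T_pref * v_fol);
    if (gterm > gap_accel_cap) gterm = gap_accel_cap;
    double a_f = k_speed * (bv - v_fol) + gterm;
    if (noise_sd > 0) a_f += R::rnorm(0.0, noise_sd);
    a_f = clip(a_f, f_amin, f_amax);

    v_lead += a_l * dt; if (v_lead < 0) v_lead = 0;
    v_fol  += a_f * dt; if (v_fol < 0)  v_fol = 0;
    x_lead += v_lead * dt;
    x_fol  += v_fol * dt;
    if (!perceive) bx += bv * dt;

    if (x_lead - x_fol - veh_len <= 0) {
      crashed = true;
      ts.push_back(t + dt); xl.push_back(x_lead); vl.push_back(v_lead);
      xf.push_back(x_fol); vf.push_back(v_fol);
      break;
    }
    if (x_fol >= trial_length) {
      ts.push_back(t + dt); xl.push_back(x_lead); vl.push_back(v_lead);
      xf.push_back(x_fol); vf.push_back(v_fol);
      break;
    }
  }

  return List::create(
      _["t"] = ts, _["x_lead"] = xl, _["v_lead"] = vl,
      _["x_fol"] = xf, _["v_fol"] = vf,
      _["glance_onsets"] = onsets, _["sched_o"] = sched,
      _["crashed"] = crashed,
      _["o_log_sum"] = o_log_sum, _["o_log_n"] = o_log_n);
}
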