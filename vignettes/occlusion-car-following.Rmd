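---
title: "Simulating and analysing occluded car following"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing occluded car following}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occlusioncf)
```

## The scientific problem

Drivers faced with visual distraction compensate: when their eyes leave the
road for longer, they leave a longer time headway to the vehicle ahead.
Task-difficulty-homeostasis accounts of car following formalise this as the
driver regulating the difference between task demand (indexed by time
headway) and capability (degraded by distraction) around a preferred level.
The self-paced visual occlusion paradigm makes both sides of that balance
measurable: the driver's view is masked except for brief (300 ms)
self-requested glances, so the self-chosen occlusion duration is a direct
record of how much visual input the driver is willing to forgo, while time
headway is a direct record of the safety margin they maintain.

`occlusioncf` provides (i) a seeded simulator for such experiments and
(ii) the complete analysis pipeline for them. The pipeline is usable on any
trial logs in the package's delimited schema, simulated or not.

## The generative model

**Leader.** The lead vehicle tracks a piecewise-constant target speed under
proportional control, `a = clip(gain * (v_target - v))`. A new target holds
for each 10 s segment and is drawn without replacement from
\{0, 30, 40, 50, 60, 70, 80\} km/h, the 7-value set being reshuffled
whenever exhausted, so each consecutive block of seven segments is a
permutation of the set. Trials end when the follower has progressed 2000 m.

**Follower control.** The follower acts on a *believed* leader state:
refreshed to truth whenever vision is available and dead-reckoned at the
last perceived speed during occlusion. Acceleration is a linear
speed-plus-gap tracker on that belief,

    a = clip( k_speed * (v_hat - v) + g + eps ),
    g = min( k_gap * (gap_hat - T_pref * v), gap_accel_cap ),

with `eps ~ Normal(0, noise_sd)` per integration step. The cap on the
closing side of the gap term encodes unaggressive approach behaviour (the
original task instructed drivers to minimise fuel consumption, which
discourages hard accelerations); braking is limited only by `accel_bounds`.
Without the cap the pure linear law is unstable at the large perturbations
the 0 km/h leader segments create: ~100 m gaps open, the saturated gap term
drives the follower to >25 m/s closing speeds, and a large fraction of
trials end in collisions even with full vision. At equilibrium
(`gap = T_pref * v`, `v = v_lead`) the cap is inactive, so the stationary
behaviour and the local linearisation are those of the plain linear
tracker.

**Headway adaptation.** The preferred headway responds to the running
geometric mean of the trial's realized occlusion durations, restarted at
`o_base` at each trial start. Two variants are implemented:

* *baseline-independent*: `T' = T0 + c * o_mean` — the headway increase is
  proportional to mean occlusion duration alone;
* *baseline-relative*: `T' = TH' * (m_d^3 + 1)` with
  `m_d = o_mean / hoogendoorn_md_scale` — the increase scales with the
  undistracted headway `TH'`. The mapping from occlusion duration to the
  task-difficulty index is not uniquely determined by the underlying
  theory; a linear map with a 1 s scale is the minimal choice, and it is
  exposed as a parameter.

**Glance scheduling.** At each glance onset the driver perceives the
current headway `T(t_g)` and commits to the next occlusion duration

    o = clip( o_base + beta * (T(t_g) - T') + nu, o_min, o_max ),
    nu ~ Normal(0, glance_noise_sd),

so a larger-than-preferred headway buys a longer eyes-off interval. The
perceived headway entering this law uses `gap / max(v, 5 m/s)`: at
walking-pace or standstill the relevant eyes-off budget is the time to
cover the gap at a modest resuming speed. (A naive `gap / v` explodes as
`v -> 0`, which would make a stopped, blind driver schedule *maximal*
occlusions exactly when frequent glancing is needed; early versions of the
simulator showed this single choice inflating occluded headways by 50% or
more.)

**Crashes.** A trial is flagged crashed and terminated when the
bumper-to-bumper gap (vehicle length 4 m subtracted from the position
difference) reaches zero. Crashed trials are kept in the dataset and
excluded from aggregates by default; the exclusion is switchable
(`include_crashed`).

## Default parameters and how they were chosen

The experiment design constants are fixed by the paradigm: 18 subjects,
4 trials per condition, 2000 m trials, 10 s leader segments, the 7-value
target set, 300 ms glances. Everything else falls into two groups.

*Control parameters* (leader gain 1.2 /s and bounds (-2.5, 2.5) m/s²;
follower `k_speed` 2.5 /s, `k_gap` 0.6 /s², `gap_accel_cap` 6 m/s²,
bounds (-3, 3) m/s², `noise_sd` 1 m/s²) were calibrated once to produce
plausible trajectories: the leader completes its largest target change
(0 to 80 km/h) within one segment to 1 km/h; decelerations stay subtle;
the closed loop is overdamped with a headway settling time of a few
seconds; and crash rates land at a few per 144 trials, the order observed
in human experiments of this design.

*Population parameters* describe between- and within-subject
heterogeneity, log-normal throughout: `T0` median 1 s (sdlog 0.35) —
one second is the standard first approximation for preferred unoccluded
headway; `o_base` median 2 s (sdlog 0.45); adaptation gains `c` and `beta`
median 1 (sdlog 0.18); per-trial preference jitter sdlog 0.15; glance
scheduling noise 0.1 s. The dispersion values were calibrated against the
dispersion statistics reported for human data in this paradigm — the
variance explained by the aggregate headway/occlusion fit (~84%), the
overall median per-trial detrended correlation (~0.56), and visible spread
in per-subject symmetric-regression slopes — because with deterministic
gains and scheduling the synthetic data is far cleaner (R² > 0.95,
correlations ~1) than any human data. Medians of 1 for `c` and `beta`
preserve the one-to-one adaptation laws at the population level.

## The analysis pipeline

1. **Preprocessing** (`trim_and_filter`): the first and last 300 m of each
   trial are discarded (standing start; end-of-trial coasting), as are all
   samples with ground speed below 1.0 m/s (which would otherwise produce
   extreme headway values). Headway is bumper gap over follower speed.
2. **Per-subject aggregates** (`summarize_subjects`): geometric means of
   pooled filtered headway samples per condition (`T_hat_0`, `T_hat_D`)
   and of pooled occlusion durations (`o_hat_D`); derived
   `delta_T = T_hat_D - T_hat_0` and `delta_rel = delta_T / T_hat_0`.
   Pooling is at the sample level by default (the geometric mean of the
   time series), with mean-of-trial-means as an option.
3. **Between-subjects comparison** (`compare_models`,
   `fit_headway_slope`): Spearman correlations of `delta_T` and
   `delta_rel` with `o_hat_D`; Fisher-z intervals with SE `1/sqrt(n-3)`
   applied to the Spearman coefficients; the difference interval by Zou's
   method for overlapping dependent correlations with the overlap
   correlation taken from the data; an OLS fit of `delta_T` on `o_hat_D`
   with a joint F-region test of the identity line (slope 1, intercept 0)
   rather than two marginal tests, since "one-to-one adaptation" is a
   statement about the line, not about each coefficient separately.
4. **Capability** (`capability_estimate`): `C_hat = 1/(o_hat + T_hat_0)`,
   reducing to `C0 = 1/T_hat_0` with no distraction.
5. **Within-trial analysis** (`glance_analysis`): headway and the next
   occlusion duration sampled at glance onsets; Theil-Sen trends over
   onset *time* subtracted from both signals (time, not glance index, is
   the natural regressor for drift, and the median-of-pairwise-slopes line
   is insensitive to the occasional wild headway value); per-trial
   Spearman correlations of the residual pairs; exact two-sided binomial
   sign tests (zero correlations count as non-positive, strictly) at trial
   and subject level; per-subject Passing-Bablok fits of pooled detrended
   pairs — a symmetric errors-in-both-variables estimator, appropriate
   because neither signal is experimentally controlled and their error
   variances are unknown.

## Numerical choices

* Integration: explicit Euler at `dt` = 0.01 s. The dynamics are heavily
  overdamped; halving `dt` changes trajectories negligibly, and the suite
  pins the compiled loop against a plain-R reference integrator.
* Scheduled occlusion durations are quantized to the integration grid, so
  onset differences minus the glance duration recover the scheduled values
  exactly — the glance record is self-consistent to clock precision.
* Onset headways are linearly interpolated between the two nearest
  retained samples; onsets whose neighbourhood was trimmed or
  speed-filtered are dropped.
* Exact binomial p-values sum all outcome probabilities not exceeding that
  of the observed count (equivalently, doubling at p0 = 1/2, capped at 1).
* Passing-Bablok: pairwise slopes for distinct x, slopes equal to -1
  discarded, estimate = median order statistic shifted by the count of
  slopes below -1, confidence bounds from the standard
  normal-approximation ranks. For an even slope count the two central
  (shifted) values are averaged arithmetically, which is why exact
  reciprocal symmetry is tested at odd slope counts.
* Initial conditions: both vehicles at the first target speed, bumper gap
  `T_pref * v` floored at 5 m (the floor guards the degenerate start when
  the first target is 0 km/h); the first 300 m trim removes the influence
  of this choice from every analysis.

## What the generator does and does not emulate

The simulator reproduces the structure of the paradigm — paired kinematic
series, self-paced glance events, the two task conditions, per-subject
preference heterogeneity, crashes — and, under default calibration, the
qualitative findings: a strong baseline-independent aggregate relation, a
clearly positive within-trial detrended covariation in essentially all
trials, and symmetric-regression slopes spread around 1.

It does not emulate: steering or lateral control; the fuel-consumption
incentive (beyond its imprint on the control law's unaggressive approach);
perceptual thresholds in gap/speed estimation (belief is exact at
glances); learning across trials; or any cognitive-distraction component.
Passing synthetic checks therefore shows internal consistency of the
method chain, not external validity for human data.

One emergent property deserves emphasis: because the glance law makes
long-headway states persist longer (the driver schedules a long occlusion
exactly when headway is large) while short-headway states are corrected
quickly, the *time-weighted* mean headway sits slightly above the
homeostatic set point, and the realized aggregate slope of `delta_T` on
`o_hat_D` is approximately `c * (1 + h)` with `h` around 0.05 under the
default leader profile (it vanishes for a constant-speed leader). This is
a genuine prediction of the adaptation laws, not an integration artifact;
it means slope estimates from occlusion experiments should be read as
upper bounds on `c` whenever the lead vehicle's speed varies strongly.

## Limitations

* The control law is the simplest law with the required equilibrium;
  human longitudinal control has anticipation and nonlinearities it lacks.
* Whether drivers dead-reckon the unseen leader at constant speed is an
  assumption of the belief model, not an established fact.
* The baseline-relative variant's mapping from occlusion to the
  task-difficulty index is a modelling choice; with the default 1 s scale
  and realistic occlusion durations it produces very long preferred
  headways, which is acceptable for model discrimination but not a
  calibrated account of that model family.
* Analysis defaults (crash exclusion, sample-level pooling) mirror common
  practice but the true exclusion rules of human studies are often
  unreported; both are switchable and logged.

## Reproducing an analysis

```{r, eval = FALSE}
ex <- simulate_experiment(population_spec(master_seed = 1))
report <- analyze_experiment(ex)
print(report)
```

The `analysis/` directory contains the same workflow as numbered scripts
(simulate; aggregate analysis; glance analysis; model discrimination by
replicate simulation), writing tables under `results/`. The replicate
studies in the test suite use 50 experiments of 144 trials each; the
discrimination scripts use 20 per variant to keep runtimes at a minute.
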