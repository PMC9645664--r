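---
title: "Models and methods: adaptive LQG reaching and decay-timescale analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: adaptive LQG reaching and decay-timescale analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachadapt)
```

# The scientific problem

When people reach while holding a robotic handle, a lateral force field
proportional to forward hand speed (`Fx = theta * vy`) deflects the movement.
A constant lateral background load (`phi`), applied before and throughout the
trial, can act as a contextual cue for which field to expect. Two behavioural
read-outs separate the timescales of adaptation:

* **initial angle** — the direction of the hand at one third of the reach
  distance, measured ~100–150 ms after reach onset, before feedback
  corrections have had time to adapt; it reflects *anticipation* formed
  across trials;
* **path length** — the integral of hand speed over a 600 ms window, which
  additionally reflects *within-trial* feedback corrections.

The package implements (i) an adaptive state-feedback (LQG) simulator of
this task, (ii) generators for the three experimental schedules
(opposite-direction contexts; magnitude cues; sequential magnitude
introduction), (iii) the kinematic metric pipeline, and (iv) the statistical
machinery: single/dual-rate exponential decay fits with BIC selection, Wald
and participant-bootstrap confidence intervals, paired tests with a
normal-approximation power formula, and random-intercept mixed models. A
synthetic-cohort generator with planted ground truth makes every stage
testable end to end.

# The plant

The hand is a planar point mass (default 1 kg) driven by a commanded force
that passes through a first-order actuator lag (default tau = 0.1 s). The
state is `(px, py, vx, vy, fx, fy)`. Continuous dynamics are discretized
exactly with the matrix exponential at `dt = 0.01` s. External lateral
forces — the background load and the velocity-dependent field — act on
lateral acceleration through the exact zero-order-hold input column of that
channel, held at their start-of-step value. Two consequences matter:

* a constant background load is *exactly* compensable at equilibrium
  (holding still against `phi` with actuator force `-phi` is a fixed point of
  the discrete map, to machine precision);
* the believed field enters the dynamics matrix linearly,
  `A(theta) = A + theta * G e4'`, so the sensitivity of the one-step
  prediction to the field gain is exactly `G * vy`. The finite-difference
  test in the suite confirms this to 1e-8.

Defaults (mass, tau, noise) are declared, not inferred: the task geometry does not
constrain them, and all are overridable.

# The controller and estimator

The controller is finite-horizon LQG with certainty equivalence: the
believed gain `theta_hat` is inserted into the dynamics and the Riccati
recursion is solved backward over the remaining horizon (80 steps = 0.6 s
movement + 0.2 s hold). The cost has three parts:

* a full state cost over the final `hold_steps = 20` steps (arrive and hold);
* a running cost on lateral deviation (`lateral_running = 1e4` per m²) at
  every step, encoding the instruction to reach straight — without it the
  effort-optimal reach under a *known* curl field curves by tens of degrees
  to exploit the field, which is not what adapted reaches look like. With
  it, a controller that knows the field reaches within 0.8 degrees of
  straight and lands within 0.1 mm of the goal;
* command effort (`effort = 1e-2` per N²).

The weights were chosen once so that unperturbed reaches complete in about
530 ms with a bell-shaped speed profile peaking near 0.45 m/s — inside the
600–800 ms success window of the task — and were not revisited afterwards.

State estimation is a standard Kalman filter on the `theta_hat`-augmented
dynamics with the background load as a known input. In noise-free runs the
filter reduces to adopting the exact measurement.

# The adaptation models

Two learning processes update the scalar field estimate from the one-step
prediction error `e = x_measured - x_predicted`, projected on the
sensitivity `s = G * vy`:

```
theta <- theta + gamma * <s, e> / c,      c = ||G||^2 * v_ref^2
```

The constant `c` fixes the units of the learning rate: `gamma` is the
fraction of the gain error corrected per step at the reference speed
(`v_ref = 0.6` m/s, roughly the upper range of reach speed), and the update
strength grows quadratically with forward speed below it. This reading is
forced by dimensional analysis: the conventional rate ranges used below are
meaningless on the raw gradient scale for this plant, where they would move
the estimate by ~1e-5 N·s/m per trial.

* **Model 1 (offline only).** The controller is fixed for the whole trial at
  the trial-initial estimate `theta_hat_k`. The estimate is nevertheless
  updated each step with the offline rate `gamma1`, and its value at the
  final step is carried to the next trial. This produces trial-by-trial
  anticipatory adaptation only.
* **Model 2 (offline + online).** In addition, a within-trial increment
  (reset to zero at each trial's start) is updated with the online rate
  `gamma2`, and the controller is re-synthesized each step from
  `theta_hat_k` plus that increment. `gamma1` updates the parameter but
  never the within-trial controller, so Model 1 and Model 2 coincide
  exactly when `gamma2 = 0` (a tested invariant).

Three structural choices make this loop behave like the behaviour it is
meant to explain; each is a modelling commitment of this
package, documented here because the update equations alone do not
determine them:

1. **Sensory delay (0.07 s).** Updates at step `t` use the prediction error
   from 0.07 s earlier. Combined with the quadratic speed weighting, this
   concentrates within-trial adaptation *after* the initial-angle threshold
   crossing (~120 ms after onset, when forward speed is near peak), so the
   initial angle reflects the trial-initial estimate. Without the delay the
   fast timescale leaks into the initial angle and the decay analysis
   selects a dual-rate model for it.
2. **Internal-model compensation of the delay.** The delayed error is
   corrected for the estimate changes applied since the sample was taken
   (`e' = e - (theta_now - theta_then) * s`), in the spirit of a Smith
   predictor. A delayed integrator without this compensation overshoots
   once the per-step gain is doubled — precisely the regime probed by the
   sensitivity analysis — and produces non-monotone path series.
3. **Credit assignment.** The offline update references errors to the model
   the trial was *planned* with (`theta_hat_k`), not to the online-corrected
   estimate. Otherwise online corrections suppress the very errors that
   drive consolidation, and trial-by-trial learning stalls in Model 2.

## Learning-rate schedules

The offline rate decays from 0.001 toward 0 and the online rate rises from
0 toward 0.2, each with first-order trial dynamics; the rate constants are
0.02 (offline) and 0.4 (online) per trial. The assignment of constants to
schedules (slow offline decay, fast online engagement) is a package
convention, configurable via
`learning_rates()`. `scale_learning_rates()` doubles or halves every
constant for the sensitivity analysis.

# The reference simulation and its signature

`reference_conditions()` fixes the conditions of the package's headline
model analysis: a 75-trial constant-field session (`phi = 4` N,
`theta = 13` N·s/m), the default plant with motor noise 0.5 N and
observation noise 1e-4, and the default learning-rate schedules. The noise
level was calibrated once so that trial-to-trial metric variability is
~0.7 degrees of initial angle and ~1.2 mm of path length; an entirely
noise-free run makes BIC selection degenerate (any structured residual
favours the five-parameter model), while much larger noise buries the fast
path-length component. As in group-level analyses of human cohorts, decay
models are fitted to metric series averaged over replicate sessions
(`average_session_metrics()`, three runs by default).

Under these conditions the signature that motivates the whole exercise
holds and is asserted by the test suite:

* Model 2: BIC selects a *single*-rate decay for the initial angle and a
  *dual*-rate decay for path length, with the fast rate at least ten times
  the slow rate and non-overlapping Wald intervals;
* Model 1: single-rate for both metrics;
* the selections are invariant to doubling or halving all learning-rate
  constants.

# Kinematic pipeline

The pipeline order is fixed: zero-phase Butterworth filtering (dual-pass,
4th order, 50 Hz cut-off at 1 kHz) → 4th-order central finite differences
(one-sided 4th-order stencils at the edges) → onset detection (first exit
from a 0.5 cm start-target radius; the radius is a configurable convention) → metrics. Filter padding is reflective and sized to
ten cut-off periods, which keeps edge transients below 1e-9. Threshold
crossings are linearly interpolated between samples. Simulator output at
100 Hz is analysed without the 50 Hz filtering stage (the filter is for
1 kHz recordings; `filter_cutoff_hz = NULL`).

Initial angles are signed CCW-positive. For grand averages across
clockwise and counter-clockwise fields, `normalize_angle_sign()` negates
the direction whose early-trial mean is negative, mapping both onto a
positive decay. Verbal descriptions of this pooling are easy to get
backwards (which direction gets negated); the early-mean rule is this
package's declared, testable behaviour.

# Decay models, BIC and uncertainty

The trial series are fitted by Gaussian maximum likelihood (equivalently
nonlinear least squares, via `minpack.lm`) to

```
single: y = a0 + a1 exp(b1 x)
dual:   y = a0 + a1 exp(b1 x) + a2 exp(b2 x)
```

with rates constrained non-positive (negative = decay) and components
ordered so `b1` is slow and `b2` fast. Dual-exponential likelihoods are
multimodal, so the dual fit multi-starts over a grid of fast rates
{-0.2, -0.5, -1, -2} and slow rates {-0.005, -0.02, -0.05}. The selection
criterion is `BIC = N log(RSS/N) + k log N` with k = 3 or 5; the model with
the smaller value wins and exact ties break toward the single model. A zero
RSS is floored at the smallest positive double. The residual sum of
*squares* is the quantity consistent with the Gaussian MLE machinery, and
is what `bic()` implements.

Parameter uncertainty comes from two routes, deliberately kept independent:
Wald intervals from the NLS parameter covariance (Gaussian approximation,
z quantiles), and a participant bootstrap that resamples participants with
replacement, averages the resampled series, refits, and takes percentile
intervals; non-converged refits are discarded and counted. The test suite
checks ~95% Wald coverage by simulation and that the true rates fall inside
bootstrap intervals in at least 90% of synthetic cohorts. Wald intervals on
the fast rate run 1–2 points below nominal at these sample sizes — the
usual curvature effect for nonlinear models — which is inside the band the
checks allow.

# Paired tests, power, mixed models

`paired_t()` computes the classical paired t statistic from the difference
vector with explicit sidedness (analyses of this task mix one- and
two-sided tests, so sidedness is never implicit here). `effect_size_pooled()` divides the mean
difference by the SD of the pooled data. `power_paired_normal()` implements
the normal-approximation power of a one-sided paired comparison,
`1 - pnorm(qnorm(1 - alpha) - d_bar / (sigma / sqrt(n)))`, with
alpha = 0.005 by default; at `d_bar = 0` it returns alpha exactly. Note the
effect size uses the pooled SD while the power formula uses the SD of
differences, so reported powers are not recoverable from reported effect
sizes alone — the function takes `(d_bar, sigma, n)` directly.

`fit_random_intercept_lmm()` fits `Y = X b + s_j + e` with a participant
random intercept by REML (ML available), covering the two designs used in
the magnitude experiments: `~ magnitude * trial` on trial-level metrics and
`~ magnitude * experiment` on catch-trial angles. t statistics use
Satterthwaite degrees of freedom; the estimation method and the df method
are recorded in the fit object.

# The synthetic-data generator

`generate_cohort()` plays any schedule for a cohort of simulated
participants, building 1 kHz KINARM-like trials from a minimum-jerk forward
profile (15 cm in 0.5 s) plus two lateral lobes:

* an **anticipatory lobe** shaped like the derivative of the forward speed
  profile (early peak, zero at the endpoints), whose scale is solved so the
  measured initial angle equals the planted target exactly;
* a **corrective lobe** confined to the second half of the movement (after
  the angle threshold crossing), whose scale is solved by root finding so
  the measured path length equals its planted target.

Planted targets follow the generative model the analysis assumes: angle
magnitude `asymptote + amplitude * exp(-lambda_slow * (k-1))` plus a
participant random intercept and trial noise; path length
`L0 + p_slow * exp(-lambda_slow * (k-1)) + p_fast * exp(-lambda_fast *
(k-1))` plus noise. The anticipatory lobe itself contributes path length
(convex in the angle), so `p_slow` is floored per participant at the
trial-1 anticipatory excess — convexity then guarantees the corrective
scale is solvable (non-negative) at every trial. Catch trials carry the
mirror-image anticipatory lobe and no corrective target; the measured-force
channel is the negated commanded background plus noise, matching the
recording convention in which the sensor sees the reaction force.

Defaults (amplitude 14°, asymptote 6°, rates 0.02 and 0.8 per trial, noise
1.5° / 4 mm) put the cohort in the regime the pipeline is meant to resolve:
a 75-trial series starting near 20° and settling near 6°, with a
fast-to-slow rate ratio of 40. A zero-noise cohort run through the full
pipeline returns the planted rates to 1e-3 (an asserted test); with the
50 Hz filtering stage included the fast rate shifts by well under 0.05
because filtering slightly shortens strongly curved early trials.

What the generator does *not* emulate: magnitude-cue interference between
motor memories, EMG, biomechanical nonlinearity, or any coupling between
the angle and path targets beyond the anticipatory-lobe geometry. Passing
tests on synthetic cohorts therefore validate the *pipeline*, not claims
about human data.

# Numerical choices and degenerate inputs

* Constant series fit as `a0 = mean, a1 = 0` with the rate unidentified at
  zero, flagged converged (the degenerate answer is exact).
* Non-converged fits are returned with `converged = FALSE`, never silently
  wrong; `select_model()` falls back to the converged candidate and errors
  if neither converged.
* Optimizer tolerances: parameter tolerance 1e-10, function tolerance
  1e-12, 500 iterations (`nls.lm`).
* Trial tables are serialized with 17 significant digits and parsed with
  base R's correctly rounded converter, so CSV round trips are bit-exact.
* Trials that never leave the start target or never cross the angle
  threshold yield `NA` metrics from the tidy wrapper (the low-level
  functions raise typed errors).

# Problem sizes in the checks

The test suite runs the reference 75-trial sessions with three-run
averaging for both model variants and the doubled/halved schedules; decay
recovery uses 50 cohorts of 18 participants with 200 bootstrap iterations
each, and Wald coverage uses 1000 single-series replicates (the 10,000
bootstrap iterations of a full analysis are an argument, not a default).
These sizes give stable pass/fail behaviour at the calibrated noise levels
while keeping a complete run in minutes on one core.

# Known limitations

* The simulator's asymptotic adaptation level depends on the learning-rate
  normalization constant `v_ref`; it is a declared unit convention, not a
  fitted quantity.
* Certainty-equivalence LQG with a scalar uncertain gain: no
  signal-dependent noise, no model-structure uncertainty, no co-contraction.
* The magnitude-cue interference seen in the second and third experimental
  designs is not modelled; the schedules and analysis paths for those
  designs are provided, the mechanism is not.
* Wald intervals on fast rates are mildly anti-conservative at N = 75; the
  bootstrap route is preferred for reporting.
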