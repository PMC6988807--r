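---
title: "Methods: Bayesian observer analysis of smooth-pursuit initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian observer analysis of smooth-pursuit initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`pursuitbayes`, in the spirit of the methods sections of the analysis
packages it resembles: what is assumed, what is a free choice and why it was
made, and what the validation suite does and does not establish.

## The Gaussian observer model

The core model treats pursuit initiation as a report of a maximum a
posteriori (MAP) direction estimate. The measurement of the target direction
is Gaussian, $\theta_m \sim N(\theta_s, \sigma_m)$, the direction prior is
Gaussian, $N(\theta_p, \sigma_p)$, and the posterior mode is the
precision-weighted average

$$\hat\theta = w\,\theta_m + (1 - w)\,\theta_p, \qquad
  w = \frac{\sigma_p^2}{\sigma_p^2 + \sigma_m^2}.$$

Because $\theta_m$ varies across trials, the MAP estimate has mean
$w\,\theta_s + (1-w)\,\theta_p$ and standard deviation $w\,\sigma_m$. Both
the attraction of pursuit toward the prior and the reduction of its
variability are therefore controlled by the single shrinkage weight $w$;
this coupling is what the bias--precision correlation analysis tests.

Assumptions worth stating explicitly:

* **Linear angle arithmetic.** All angles are degrees, counterclockwise
  positive, 0° rightward. Directions are *unwrapped* into the 360° interval
  centred on the relevant reference (the target direction, or the condition
  median) before any mean, SD or regression. This is valid because observed
  direction spreads are far below 180°; the wide-prior block's 240° target
  separation is handled by unwrapping each pursuit direction around its own
  target before differencing.
* **Gaussianity.** Likelihood and prior are Gaussian on the (unwrapped)
  angle line, not von Mises on the circle. At the spreads involved
  (σ ≲ 35°) the difference is negligible relative to measurement noise.
* **The eye reports the posterior mode.** Motor noise can be added
  downstream (`motor_noise_sd`), in which case it adds to the MAP variance
  in quadrature; it defaults to 0.

## The eight-parameter fit

`fit_observer()` estimates five likelihood SDs (one per distinct target
direction; the central direction is shared between blocks), one
multiplicative low-contrast factor $c \ge 1$, and one prior SD per block,
from the 24 condition summaries (12 means, 12 SDs), by minimising the plain
sum of squared errors with means and SDs equally weighted in raw degrees.
The prior mean $\theta_p$ is fixed at the known central direction rather
than fitted: the task defines it, and freeing it only degrades
identifiability.

Numerical choices:

* Parameters are optimised on the log scale with box bounds
  $\sigma_m \in [0.5°, 90°]$, $c \in [1, 10]$,
  $\sigma_p \in [1°, 10^6°]$, using `optim(method = "L-BFGS-B")`.
* 20 Latin-hypercube starts (seeded, via `lhs`) plus one moment-based start
  (wide-block high-contrast SDs read off $\sigma_m$, the wide low/high SD
  ratio reads off $c$, the narrow-block shrinkage reads off $\sigma_p$).
  The best local minimum is polished at tight tolerance
  (`factr = 10`). On noise-free inputs the generating parameters are
  recovered to well below 0.1%.
* The wide-block prior SD is retained as a free parameter but is not
  practically identifiable once the prior is effectively flat: any
  sufficiently large value gives $w \approx 1$. Its estimate drifting to
  the upper bound is expected and not flagged; its numerical value should
  never be interpreted beyond "flat".
* Any *other* parameter landing on a bound raises a warning flag
  (`at_bound`), since that indicates a degenerate data set rather than a
  meaningful estimate.
* The fit is equivariant to adding a constant to all direction labels
  (checked in the test suite), so the choice of the prior direction as 0°
  in simulations is without loss of generality.

## What the synthetic-data generator emulates

`simulate_session()` produces the two-block design: narrow-prior blocks
(prior direction and ±15°, the prior direction twice as often, 252 trials)
and wide-prior blocks (three directions 120° apart, 378 trials), alternated
`n_block_reps` times per session. The default of four repeats per block
type (2520 trials/session) mirrors a typical single-day experiment and is
what makes per-cell SD estimates (~250 central-direction trials per
contrast) stable enough for the session-level analyses. High and low
contrast are randomly interleaved in equal proportion within each block.

Each trial's pursued direction is drawn from the generative observer above,
with the block's prior SD and the contrast-scaled likelihood SD. The eye
trace realisation is *not* constrained by the model and uses deliberately
simple kinematics:

* velocity is zero until the trial's latency, then rises along a
  half-logistic curve reaching 90% of `gain × target_speed` in
  `rise_ms = 60` ms. Only open-loop statistics matter downstream, so the
  onset shape is a free choice;
* latency is Gaussian per trial (means 120 ms high contrast / 160 ms low,
  SD 15 ms, clamped to (50, 400) ms) and gain is Gaussian (mean 1,
  SD 0.1). These are plausible primate values, configurable, and nothing
  downstream asserts them;
* white velocity noise (`vel_noise_sd`, default 1 deg/s per component) is
  added before integration to give the preprocessing and template fit
  realistic work;
* with probability `saccade_prob` (default 0.15) a trial receives one
  30-ms, 200-deg/s raised-cosine saccadic velocity pulse at a uniform
  random onset in [0, 370] ms, exercising detection and exclusion;
* optional single-trial adaptation shifts the pursued direction by
  `adaptation_shift` degrees toward the previous trial's target direction
  (within the same block segment), so the adaptation statistic has a known
  ground truth of twice the shift;
* the optional `sigma_m_timecourse = c(A, tau)` makes the likelihood SD
  decay within a trial, $\sigma_m(t) = \sigma_m (1 + A e^{-t/\tau})$, and
  the pursued direction relax from an early, strongly prior-weighted MAP
  toward the final MAP. This exists to exercise the timecourse analysis;
  real sensory integration dynamics are surely richer.

One master seed spawns an independent RNG stream per trial, so individual
trials are bit-reproducible regardless of session reordering or subsetting.

The generator does **not** emulate: dot-level random-walk stimulus noise
(its effect enters only through $\sigma_m$), catch-up saccade dynamics or
post-saccadic pursuit enhancement, blinks, drift or measurement noise of a
video eye tracker beyond white velocity noise, closed-loop corrections
after ~250 ms, or fixation/reward behaviour. Passing tests therefore
establish that the *analysis chain is correct and well calibrated on data
satisfying its own assumptions* — not that those assumptions hold for any
particular recording.

## Preprocessing conventions

* **Zero-phase filtering.** Positions are low-pass filtered at 20 Hz
  (second-order Butterworth) forward and backward, so features are not
  delayed and latency estimates are unbiased; the effective magnitude
  response is the squared single-pass response,
  $\approx 1/(1+(f/f_c)^4)$. The implementation pads with an odd-symmetric
  reflection and initialises each pass at the steady state of its first
  sample, which makes the DC gain exactly 1 (a constant trace passes
  through bit-identically) and agrees with the reference two-pass
  implementation in SciPy to ~10⁻⁵ deg away from the trace edges. At
  100 Hz the measured two-pass attenuation is ≈ 0.0013 versus the analog
  prediction 0.0016; the difference is the bilinear frequency warping of
  any digital Butterworth design and is immaterial five octaves into the
  stopband.
* **Differentiation** is central-difference (one-sided at the endpoints),
  exact for linear ramps.
* **Saccade detection** flags epochs where radial speed exceeds a 50-ms
  running-median baseline by more than 30 deg/s for at least 5 ms. The
  criterion is a package choice (detection thresholds are rarely published)
  and every threshold is an argument.
* **Trial exclusion** removes trials with any detected saccade overlapping
  the closed window −100 to 250 ms from motion onset. The window default
  follows the convention of starting at −100 ms; a 0-ms start is available
  via the `window` argument. Exclusion is idempotent and logged.

## Open-loop decomposition

Each condition (direction × contrast × block, pooled across block repeats)
gets a velocity template: the across-trial mean horizontal and vertical
velocity from −20 to +100 ms around the condition's average pursuit
latency, rotated so the template's mean direction is exactly 45°. Rotating
trials into this oblique frame before fitting is what makes the
trial-level direction estimate unbiased at the condition direction (both
components carry signal, so component-wise scale noise is symmetric).

The average latency anchoring the window is estimated as the time where the
trial-averaged speed first exceeds 10% of its value at +250 ms, refined by
fitting a line to the 10–50% portion of the rise and extrapolating to zero
speed. No standard procedure exists for this; the rule is documented here
and recovers generator latencies to within ±5 ms.

The per-trial fit slides the two template components jointly (shift $\tau$,
±50 ms) and scales them independently ($a$, $b$), minimising the summed
squared error of both components. For fixed $\tau$ the scales are
closed-form least squares, so the problem is separable: $\tau$ is found by
exhaustive 1-ms grid search followed by parabolic refinement of the SSE
minimum, with the scales recomputed at the refined shift on linearly
interpolated samples. This replaces the black-box mesh-adaptive direct
search used in earlier work by something deterministic, exactly testable,
and exact for this problem class. Window samples that would leave the
recorded trace are dropped from the sums (they never occur with the default
geometry). A trial's direction is $\mathrm{atan2}(b, a)$ rotated back to
the stimulus frame; its scalar gain is $(a+b)/2$ (no standard scalar
definition exists); `variance_explained` is $1 - \mathrm{SSE}/\mathrm{SST}$
over the fit window, and trials at or below 0.70 are excluded from
analysis. Degenerate (all-zero) templates are an error; a shift landing on
the search bound is flagged per trial.

Session-level inclusion then drops per-trial direction outliers beyond 3
median absolute deviations within their condition (an explicit stand-in for
an unspecified outlier rule) and retains the session only if strictly more
than 70 included central-direction trials remain in each block type.

## Session statistics

The bias measure is the direction-difference ratio: the separation of the
mean pursuit directions of the two outer targets divided by the separation
of the targets themselves (30° narrow, 240° wide); values below 1 indicate
attraction toward the central direction. The precision measure is the
robust SD (3-MAD trimmed) of central-direction pursuit directions, compared
across blocks as SD(narrow)/SD(wide). Ratios are tested against 1 by a
two-sided one-sample t-test on logs; ratio pairs are correlated by
Spearman's rank test. The single-trial adaptation statistic is the mean
pursuit direction of central-direction trials whose previous target was
counterclockwise of it minus the mean of those whose previous target was
clockwise (previous-trial contrasts pooled); its generative expectation is
twice the per-trial shift. No multiple-comparison correction is applied
anywhere; raw p-values are reported.

## Timecourse analysis and the permutation test

Per-time-point direction is the instantaneous velocity direction
$\mathrm{atan2}(v_v, v_h)$, masked below a 1 deg/s speed floor (the
direction of a near-zero vector is noise); a cumulative-displacement
variant would be smoother but mixes time points, so the instantaneous
estimator is the default. Bias-ratio and SD curves are computed per
condition from 0 to 250 ms, smoothed with a 10-ms boxcar, and masked
wherever fewer than `min_n` trials contribute.

Curves are compared across prior conditions with a two-sided cluster-based
permutation test: per-time paired t statistics, cluster-forming threshold
$|t| > t_{1-\alpha_c/2, n-1}$ with $\alpha_c = 0.05$, cluster mass
$\sum |t|$, and a null built from 1000 random within-session sign flips of
the paired differences. The cluster p-value counts the observed labelling
among the permutations, $p = (1 + \#\{\max\text{-mass} \ge m\})/(N+1)$, so
p is always in (0, 1] and exact under exchangeability. Threshold,
permutation count and smoothing width are free choices (none are standard
across labs) and all are arguments. Calibration in the test suite: the
family-wise false-positive rate over 500 null simulations at 20 sessions
stays at or below 0.08 (nominal 0.05), and a 3-standard-error offset
planted over 0–150 ms is detected in >90% of runs at 30 sessions.

## Validation problem sizes

The test suite validates each stage at sizes chosen to keep Monte-Carlo
error well below the tested tolerances: 10⁵ draws for generator moments,
10⁶ draws for the MAP-moment oracle, 100 random queries against a
10⁻⁴-degree posterior-grid argmax, 500 synthetic trials for template
recovery (median absolute errors below 1 ms / 0.02 / 0.02 at 1 deg/s
noise), 20 full-scale simulated sessions for the end-to-end bias/precision
asymmetry, and 500 + 100 simulations for permutation-test calibration and
power.

## Known limitations

* The analysis treats directions linearly after unwrapping; geometries with
  spreads approaching 180° would need circular statistics throughout.
* The latency-anchoring rule and the saccade criterion are package choices;
  on real data both should be checked against the recording's noise floor.
* The wide-prior SD is reported but not identifiable beyond "flat".
* The generator's trace kinematics are schematic; quantities that depend on
  the exact velocity profile outside the open-loop window (e.g. closed-loop
  gain) are out of scope.
* Observer fits on single noisy sessions recover the narrow-prior SD with
  considerable spread (it trades off against the likelihood SDs); stable
  estimates need session averaging, as in the worked example's
  multi-session pipeline.
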