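# pursuitbayes

Simulation and analysis of open-loop smooth pursuit eye movements under
switching direction priors.

When a primate tracks a moving dot patch, the first ~100–250 ms of pursuit
(the "open-loop" period) is driven purely by feedforward sensory signals. If
the pursuit system performs Bayesian inference, an expectation about the
target's motion direction should do two things to pursuit initiation under
weak sensory evidence: *bias* its direction toward the expected direction,
and *reduce* its trial-to-trial variability. `pursuitbayes` implements the
full analysis chain needed to test this on a two-block pursuit experiment —
and, because such data sets are rarely deposited, a generative simulator
that produces synthetic sessions with the same statistical structure, so
every stage is testable end to end.

## The model

On each trial the observer measures the target direction with Gaussian
noise, θ<sub>m</sub> ~ N(θ<sub>s</sub>, σ<sub>m</sub>), and holds a Gaussian
prior N(θ<sub>p</sub>, σ<sub>p</sub>) over directions. The maximum a
posteriori direction estimate is the precision-weighted average

&nbsp;&nbsp;&nbsp;&nbsp;θ̂ = w·θ<sub>m</sub> + (1 − w)·θ<sub>p</sub>,
&nbsp;&nbsp; w = σ<sub>p</sub>² / (σ<sub>p</sub>² + σ<sub>m</sub>²),

so that across trials

&nbsp;&nbsp;&nbsp;&nbsp;E[θ̂] = w·θ<sub>s</sub> + (1 − w)·θ<sub>p</sub>,
&nbsp;&nbsp;&nbsp;&nbsp;SD[θ̂] = w·σ<sub>m</sub> ≤ σ<sub>m</sub>.

A usable prior therefore simultaneously attracts the pursuit direction
toward θ<sub>p</sub> and shrinks its variability — the signature the
analysis looks for. The fitted observer has eight free parameters: five
likelihood SDs σ<sub>m</sub> (one per target direction), a multiplicative
contrast scaling factor *c* applied to σ<sub>m</sub> at low contrast, and
one prior SD per block type (narrow and wide). They are estimated by
bounded multi-start least squares from 24 data points: the mean and SD of
pursuit direction in each of the 12 condition cells (3 directions × 2
contrasts × 2 prior blocks).

## The pipeline

| Stage | Functions |
|---|---|
| Synthetic sessions | `task_config()`, `gen_params()`, `simulate_session()`, `write_session()` |
| Preprocessing | `lowpass_filter()` (zero-phase Butterworth), `differentiate()`, `detect_saccades()`, `exclude_trials()` |
| Open-loop decomposition | `estimate_session_latency()`, `build_template()`, `fit_trial()`, `decompose_session()`, `apply_session_inclusion()` |
| Session statistics | `direction_difference_ratio()`, `pursuit_direction_sd()`, `log_ratio_ttest()`, `bias_precision_correlation()`, `adaptation_statistic()` |
| Observer model | `map_estimate()`, `predict_mean_sd()`, `predict_design()`, `fit_observer()` (with `tidy()`, `glance()`, `autoplot()`) |
| Timecourse | `session_timecourse()`, `timecourse_statistics()`, `cluster_permutation_test()` |
| Orchestration | `analyze_session()`, `run_pipeline()` |

All user-facing functions take and return tibbles, so stages chain with the
pipe.

## Worked example

Simulate one full session (four alternating narrow/wide block pairs, 2520
trials) from an observer with likelihood SD 7.94°, contrast factor 1.83 and
a 34.5° narrow prior, run the analysis chain, and fit the model back:

```r
library(pursuitbayes)

cfg  <- task_config(n_trials_narrow = 252, n_trials_wide = 378, n_block_reps = 4)
sess <- simulate_session(cfg, gen_params(), seed = 1)
kin  <- sess |> preprocess_session() |> exclude_trials() |> decompose_session()
incl <- apply_session_inclusion(kin, prior_direction = 0)
fit  <- fit_observer(condition_summaries(incl$kinematics), theta_p = 0)
fit
#> Gaussian Bayesian observer fit (8 parameters, 24 data points)
#>   sigma_m (deg): 8.28, 8.45, 7.69, 7.85, 7.93
#>   contrast factor: 1.846
#>   sigma_p narrow: 30.16 deg, wide: 255.2 deg
#>   R2(means) = 0.9999, R2(SDs) = 0.9697, SSE = 10.23
```

The five fitted likelihood SDs scatter around the generating 7.94°, the
contrast factor recovers 1.83, and the narrow-prior SD lands near the
generating 34.5° (it is the least constrained parameter in a single noisy
session); the wide-prior SD is large, i.e. effectively flat. The session
statistics show the behavioural signature directly:

```r
session_statistics(incl$kinematics, cfg)$bias
#>   block  contrast ratio
#> 1 narrow high     0.995
#> 2 narrow low      0.780
#> 3 wide   high     0.998
#> 4 wide   low      0.997
session_statistics(incl$kinematics, cfg)$sd_ratio
#>   contrast sd_narrow sd_wide ratio
#> 1 high          7.01    8.26 0.848
#> 2 low          12.1    13.7  0.888
```

Direction-difference ratios below 1 mean the two outer pursuit directions
were attracted toward the central (prior) direction: the attraction is
strong in the narrow-prior block at low contrast (0.78) and absent in the
wide-prior block (≈1). The narrow block is also the more precise one
(SD ratio < 1), most clearly at low contrast.

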