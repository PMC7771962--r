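# tdaxon

Temporal-difference (TD) error models and fiber-photometry analysis of
dopamine axon signals in the striatum, for an odor-guided two-alternative
choice task with asymmetric reward sizes.

Dopamine axons projecting to the ventral, dorsomedial and dorsolateral
striatum (VS, DMS, DLS) carry reward-prediction-error-like calcium signals
whose details differ across regions: the delivered water amount at which
the response flips from inhibition to excitation (the *zero-crossing
point*) shifts along the medial-lateral axis, and post-choice activity
carries a confidence-like modulation by sensory evidence. `tdaxon`
implements the computational machinery needed to analyse such recordings
and to reason about them with a task-level TD model:

* **TD model of the task** — an agent perceiving a noisy "subjective odor"
  (Gaussian noise, sd σ in %odor) and choosing between a BIG side
  (2.2/0.8 × standard water) and a SMALL side (0.8/0.2 ×) under
  deterministic, softmax (`PB = e^{(VB/(VB+VS))/τ} / (e^{(VB/(VB+VS))/τ} +
  e^{(VS/(VB+VS))/τ}`), matching, or ε-greedy policies, with concave
  reward utility `u(R) = R^0.7`. State values come from an exact backward
  solver or a Monte-Carlo simulation; per-trial-type TD traces
  (`δ_t = r_t + V_{t+1} − V_t`, γ = 1) expose the commitment dip and the
  post-commitment confidence signal.
* **Event-kernel encoding model** — raised-cosine bases (200 ms width,
  40 ms spacing) locked to odor, movement, choice and water events,
  fitted to 20-ms-sampled photometry by lasso with trial-blocked 10-fold
  cross-validation and the 1-SE rule; variance explained and per-component
  deviance contributions.
* **Photometry preprocessing** — zero-phase 58–62 Hz FIR bandstop, 50 ms
  smoothing, 100 s moving-median detrending, significance-gated
  tdTomato (motion) regression, event-window responses, normalisation,
  and time warping for display.
* **Reward response functions** — fits of `r = k(R^α + c1·S + c2)` with
  zero-crossing estimation `(−c2)^{1/α}` / `(−c1−c2)^{1/α}`, anatomical
  regression of crossings on AP/DV/ML, and evidence/value slopes.
* **Input-ratio circuit model** — postsynaptic TD signals from an
  excitatory TD input plus a sign-flipped inhibitory input, transmitted
  with 1/10 gain below baseline; excitation:inhibition ratios (2:1, 1:1,
  1:2) shift the water-response zero crossing in the DLS→VS→DMS order.
* **Behavioral analyses** — binomial-GLM psychometrics with fixed-slope
  block shifts (`logit μ = b0 + b1 X + b2 X2`), choice bias `50 − PSE`,
  reward landscapes over bias, and trial-history bias.
* **Bootstrap model comparison** — per-animal responses in 8 trial types ×
  2 phases correlated with model values, resampled 22-per-cell, 500×.
* **Synthetic-data generator** — behavioral sessions driven by the TD
  agent and two-channel photometry built from TD impulses convolved with a
  calcium kernel plus drift, 60 Hz line noise, and shared motion
  artifacts, so the entire pipeline is testable without recordings.

Everything is tidyverse-shaped: trial tables in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` for the main result types.

## Worked example

```r
library(tdaxon)

# the calibrated softmax agent: sigma = 18 %odor, tau = 0.22
spec <- task_model(sigma = 18, tau = 0.22)
values <- solve_state_values(spec)
values
#> <state_values> (exact)
#>   V(ITI) = 0, V(OdorOn) = 0.8343
#>   V(Water|BIG) = 1.2960, V(Water|SMALL) = 0.5898, V(NoWater) = 0
#>   per-subjective-odor table: 60 grid points

# the inhibitory dip: choosing SMALL against strong BIG evidence
tr <- td_trace(spec, values, odor = 100, choice = "small", outcome = "none")
tr$delta[tr$state == "WaterPort1"]
#> [1] -0.9998663

# simulate a session and fit its psychometric function
trials <- generate_session(session_config(seed = 2), spec)
fit <- fit_psychometric(trials, joint_blocks = TRUE)
fit
#> <psychometric_fit>
#>   b0 = -3.3623, b1 = 0.0640, b2 = 0.3983
#>   PSE: block 1 52.54, block 2 46.32; shift 6.22 %odor
```

The block-2 shift is the agent's own reward-driven choice bias: with a
BIG side worth more, the softmax policy moves the point of subjective
equality several %odor toward the BIG-instructing odors, exactly the bias
the fixed-slope GLM quantifies. A circuit-model query:

```r
pv <- partial_learning_values(spec)
sapply(c("more_excitation", "balanced", "more_inhibition"), function(r)
  circuit_zero_crossing(water_response_curve(pv, circuit_params(r))))
#> more_excitation        balanced more_inhibition
#>       0.7880234       0.9654054       1.0714793
```

More excitation → smaller crossing (DLS-like units are not inhibited by
small rewards); more inhibition → larger crossing (DMS-like units need
bigger rewards to be excited).

## Package layout

| Area | Functions |
|---|---|
| TD model | `task_model()`, `solve_state_values()`, `monte_carlo_state_values()`, `td_trace()`, `partial_learning_values()`, `fit_task_model()` |
| Synthetic data | `session_config()`, `generate_session()`, `trial_td_impulses()`, `photometry_config()`, `generate_photometry()` |
| Preprocessing | `clean_trace()`, `detrend_trace()`, `subtract_motion()`, `event_responses()`, `normalize_session()`, `time_warp()` |
| Kernel model | `kernel_spec()`, `build_design()`, `fit_kernels()`, `percent_explained()`, `component_contribution()`, `kernel_profiles()` |
| Response functions | `fit_response_function()`, `zero_crossing()`, `anatomy_regression()`, `evidence_slope()` |
| Circuit model | `circuit_params()`, `transmit()`, `postsynaptic_td()`, `water_response_curve()` |
| Behavior | `fit_psychometric()`, `choice_bias()`, `reward_landscape()`, `history_bias()` |
| Model comparison | `trial_type_means()`, `trial_type_predictions()`, `bootstrap_compare()` |

The methods vignette (`vignettes/td-error-models.Rmd`) documents the
models, assumptions, parameter choices and limitations in detail.
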