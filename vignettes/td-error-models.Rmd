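---
title: "TD-error models of striatal dopamine signals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TD-error models of striatal dopamine signals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdaxon)
library(dplyr)
```

`tdaxon` analyses dopamine-axon calcium signals recorded by fiber photometry
in the striatum while mice perform an odor-guided two-alternative choice task
with asymmetric reward sizes. This vignette explains the models the package
implements, the assumptions behind them, the tunable parameters, and the
design decisions taken where the problem was genuinely open.

## The task and its state machine

A trial starts when the animal pokes an odor port. One of four odor mixtures
(coded throughout as X = % odor instructing the BIG side: 0, 35, 65, 100) is
presented; the animal must stay at least 1 s, then choose a left or right
water port and hold for 1 s before the outcome. In block 1 both sides pay a
standard drop on correct choices. In block 2 one side becomes BIG (2.2 or
0.8 x standard, p = 0.5 each) and the other SMALL (0.8 or 0.2 x standard).
Errors pay nothing; the inter-trial interval is 7 s after reward and 9 s
after an error.

The model ([`task_model()`]) walks through discrete within-trial states:
ITI, OdorOn, two subjective-odor states, two water-port states, outcome
detection (water versus no water), and amount discrimination. Two noise
sources are modelled:

* **perceptual noise** — the agent perceives a subjective odor O', drawn
  from a Gaussian centred on the presented mixture with sd `sigma` (% odor),
  discretised onto a grid (`n_subjective` = 60 uniform points, or the 4
  presented odors);
* **decision noise** — the choice between the BIG- and SMALL-side values
  `VB`, `VS` is stochastic: softmax on sum-normalised values with
  temperature `tau`, value-proportional matching, or epsilon-greedy. The
  deterministic (argmax) policy has perceptual noise only.

Reward utility is concave, `u(R) = R^alpha` with `alpha = 0.7`. State
values follow by exact backward induction (`solve_state_values()`):
`Vb = 2.2^0.7`, `Vm = 0.8^0.7`, `Vs = 0.2^0.7`; water states average the
two amounts a side can deliver; `VB(O') = fB(O') * VWB` where `fB` is the
probability that the presented odor instructed BIG given O' (a uniform
prior over the four odors); SubOdor values average `VB`, `VS` under the
policy; OdorOn marginalises over O'; the ITI value is 0. TD errors are
consecutive value differences with discount 1, the delivered reward folded
into the terminal transition so each trial's deltas telescope exactly to
the realised outcome utility.

The default parameters `sigma = 18`, `tau = 0.22` are the behavioral
calibration of the softmax model (the deterministic variant calibrates to
`sigma = 21`); they are treated as study conditions, not tuning knobs.

Two phrasings in the sources were ambiguous and are resolved explicitly:

* the matching policy is implemented value-proportional,
  `PB = VB / (VB + VS)`, which is what Herrnstein's law states; the
  anti-proportional orientation is available via `matching_inverted` for
  completeness;
* choice bias is defined from the point of subjective equality:
  `bias = 50 - pse`, positive toward BIG, which is unambiguous regardless
  of odor coding;
* the epsilon-greedy exploration rate has no defensible calibration without
  the animals' average psychometric curve, so its default (0.1) is simply a
  conventional exploration rate and should be set explicitly when that
  policy is used in earnest.

## Monte-Carlo values

`monte_carlo_state_values()` simulates the agent at steady state and
estimates each value as an empirical transition frequency times an
empirical outcome average (e.g. `VB(O') = fB_hat(O') * VWB_hat`, with
`VWB_hat` the mean utility over rewarded BIG-side trials). This estimator
mirrors the backward definition of the values and converges much faster
than raw conditional return averages; at 100,000 trials on the 4-state
grid every state agrees with the exact solver to better than 0.01 utility
units, which the acceptance suite verifies.

## What baseline-subtracted responses measure

Photometry responses are window means minus a pre-odor baseline, taken
where the state value is the ITI value (0). A baseline-subtracted window
response therefore tracks the *cumulative* TD error since trial start —
the state value itself — while individual transitions appear as phasic
deltas. Both views matter for the package's headline contrast:

* deterministic policy: every post-commitment, pre-outcome TD step is
  exactly zero, at every evidence level — no confidence signal;
* softmax policy: the post-commitment value rises monotonically with
  sensory evidence for **both** choices (the vevaiometric "X-pattern"),
  and the commitment delta is negative when the agent picks SMALL against
  strong BIG evidence (the inhibitory dip after "losing" a better option).

The same accounting explains the pre-choice asymmetry: conditioned on a
SMALL choice, the per-trial regression of pre-choice responses on evidence
is almost exactly flat, because the rare high-value trials in which strong
BIG evidence nonetheless ends in a SMALL choice cancel the mild positive
trend of the common trials. The end-to-end test reproduces this with the
full synthetic pipeline.

## Synthetic sessions and photometry

`generate_session()` draws odors uniformly, percepts from the perceptual
model, choices from the policy (block 1 uses a value table solved with
equal rewards), rewards per the schedule, and event times: reaction time is
1 s (the enforced stay) plus a log-normal excess with median 0.2 s (total
median 1.2 s), movement time log-normal with median 0.35 s, outcome exactly
1 s after water-port entry, and a short log-normal self-initiation delay
after the ITI. The paper's sources give no reaction/movement-time
distributions; log-normals are the standard positive-support choice for
rodent latencies. An optional `bias_shift_block2` shifts the agent's
block-2 percepts laterally, imposing a known psychometric shift for
recovery studies. Note that the block-2 schedule itself biases the softmax
agent several % odor toward BIG — recovering an *imposed* shift therefore
requires differencing against a zero-shift run.

`generate_photometry()` places each trial's realised TD deltas as impulses
at their events (odor detection at odor onset, percept recognition 200 ms
later, commitment at odor-port exit, outcome detection at the outcome, and
amount discrimination 200 ms after), convolves them with a peak-normalised
difference-of-exponentials calcium kernel (rise 50 ms, decay 600 ms,
GCaMP7f-like), and adds slow drift, a 60 Hz line component, white noise,
and a band-limited motion process shared with the red (tdTomato) channel.
The sampling rate defaults to 1 kHz and is configurable; the examples and
tests mostly use 100-250 Hz, which comfortably resolves the kernel while
keeping runtimes small.

The generator emulates the statistical structure the analyses assume —
event-locked transients, shared motion artifacts, drift, line noise. It
does **not** emulate licking dynamics, bleaching beyond slow drift,
hemodynamic or spectral effects, inter-animal kinematic variability, or
spiking nonlinearities, so green tests show the pipeline's correctness on
its assumed signal model, not robustness to every failure mode of real
recordings.

## Preprocessing

`clean_trace()` applies a Hamming-window FIR bandstop (58-62 Hz), centred
so it is exactly zero-phase (the filter is symmetric), then a 50 ms moving
average; edges use shrinking windows. The filter order scales with the
sampling rate (`1.6 fs` taps) so the stopband attenuation exceeds 20 dB.
`detrend_trace()` subtracts a 100 s running median; subtraction rather
than division keeps downstream responses in raw signal units, which is
what the window-minus-baseline definitions expect. `subtract_motion()`
regresses green on red during the inter-trial intervals (intercept
included) and subtracts the fitted red signal when the slope is
significant at p < 0.05, keeping the regression report. The order
clean -> detrend -> motion-subtract is near-idempotent.

`event_responses()` computes the standard windows: pre-choice (1-0 s
before odor-port exit), post-choice (0-1 s after water-port entry), and
outcome responses, with the 0.3-1.3 s post-water window as the default
(`outcome`) and the 0-1 s variant available (`outcome_early`); the
baseline is 1-0.2 s before odor onset, switchable to 1-0.2 s before water
for pre-reward-subtracted analyses. `normalize_session()` implements the
peak normalisation (mean odor-onset peak over successful trials) and
z-scoring over choice-trial windows. `time_warp()` is visualisation
support only: piecewise-linear stretching onto median reaction/movement
durations in 100 ms bins.

## The kernel encoding model

`build_design()` expresses the green trace (-1 to +7 s around odor onset,
20 ms samples, valid choice trials) as a sum of event-locked kernel
groups: odor (base, pure-BIG, pure-SMALL, mixture), movement (contra/ipsi
turn), choice (correct-BIG, correct-SMALL, error), and water (big,
medium-at-BIG, medium-at-SMALL, small), each spanning its published
window. Kernels are built from raised cosines,
`0.5 (1 + cos(2 pi (t - c)/w))` with width 200 ms and centres every 40 ms
— inside a span these tile a partition of unity, so smooth kernels are
representable without ripple. `fit_kernels()` uses cross-validated lasso
(`glmnet`), with folds blocked by trial to avoid leakage between
temporally adjacent samples and the one-standard-error rule for the
regularisation weight. Variance explained is `1 - var(resid)/var(y)`;
`component_contribution()` refits without one component's columns (same
folds, same rule) and reports the RSS increase — "deviance" for this
Gaussian model is taken as RSS, to which it is proportional at fixed
variance.

## Reward response functions and zero crossings

`fit_response_function()` fits `r = k (R^alpha + c1 S + c2)` to per-trial
outcome responses across the four condition cells (big/medium at the BIG
port, medium/small at the SMALL port), linearly in `(k, k c1, k c2)` at
fixed `alpha = 0.7`; a free-`alpha` variant scans 0.1-1.0 in 0.01 steps by
RSS (the sources do not state their optimiser; a grid is transparent and
reproducible at this resolution). Zero crossings invert the curve:
`(-c2)^(1/alpha)` under BIG-side expectation, `(-c1-c2)^(1/alpha)` under
SMALL-side; a nonpositive bracket means the response never crosses zero
(all-positive responses, the DLS pattern) and is flagged rather than
thrown. Per-trial fitting is the default (it uses all data); condition
means can be fitted by averaging beforehand. `anatomy_regression()` is an
ordinary multiple regression of crossings on AP/DV/ML coordinates;
`evidence_slope()` the per-choice OLS slope of window responses on
evidence or value.

## The input-ratio circuit model

`postsynaptic_td()` models a postsynaptic neuron receiving the TD error
through an excitatory input and its sign-flipped copy (RMTg-like) through
an inhibitory one, both transmitting below-baseline deflections at 1/10
gain. Positive deflections are then scaled by `w_exc + 0.1 w_inh` and
negative ones by `0.1 w_exc + w_inh`: with balanced weights the output is
a scaled copy of the TD input, while 2:1 and 1:2 ratios tilt the balance.
`water_response_curve()` sums the two outcome-phase TD steps — detection
(`V_W - V_WaterPort`, amount-independent) and discrimination
(`u(R) - V_W`) — through this map, using the partial-learning value table
(`VWB = (Vb + Vm + 2 Vtrained)/4`, `Vtrained = 1^0.7`), which mimics
water responses under incomplete learning of the new amounts. The exact
temporal overlap of the two steps is not published; summation over the
outcome window is the minimal faithful reading. Zero crossings shift
leftward with more excitation and rightward with more inhibition —
excitation-dominant (DLS-like) units stop being inhibited by small
rewards, inhibition-dominant (DMS-like) units need larger rewards to be
excited. Only shapes, signs and crossing order are meaningful; the output
scale is arbitrary.

## Bootstrap model comparison

`bootstrap_compare()` correlates per-animal mean responses in 8 trial
types (choice x difficulty x accuracy) x 2 phases (before/after choice)
with two models' value predictions, resampling 22 values per cell with
replacement so rare trial types weigh equally, 500 times; the p-value is
the fraction of resamples in which the second model's correlation is equal
or smaller. Cells are stratified at the animal level and phases pooled
into one correlation, matching the "22 x 8 x 2" accounting. Model
predictions are state values relative to ITI (what baseline-subtracted
responses track), conditioned on objective odor and choice.

## Numerical choices and degenerate inputs

* Psychometric GLMs use `stats::glm` (binomial, logit; IRLS tolerance
  1e-8, 100 iterations); complete separation is detected (unbounded
  standard errors or saturated fitted values) and refitted with a small
  ridge penalty, flagged on the result. A slope within 1e-8 of zero makes
  the PSE undefined and bias queries error.
* Ties in the deterministic policy split 0.5/0.5; zero-probability trial
  types error by name.
* Subjective-odor distributions that underflow (tiny `sigma`) collapse to
  the nearest grid point with a warning path.
* Zero crossings on sampled circuit curves are located by sign change with
  linear interpolation on a 0.002-unit amount grid.
* Seeds: every generator and resampler takes an explicit seed and restores
  the caller's RNG state (`withr`).

## Problem sizes used in the checks

The verification suite runs the Monte-Carlo comparison at 100,000 trials,
parameter recovery at 20,000 trials, kernel recovery on 160 trials of
250 Hz photometry with a five-group kernel set (the full thirteen-group
set is exercised functionally), bias recovery on 50-session batches of
200 + 200 trials differenced against a zero-shift batch, and the
end-to-end pipeline on six synthetic animals of 250 block-2 trials each.
These sizes give comfortable statistical margins for every asserted
property while keeping a full run to a few minutes on one CPU.

## Known limitations

* The agent is at steady state; learning dynamics across sessions are out
  of scope, as are action-value (Q) formulations and temporal discounting
  (the discount is fixed at 1).
* The Gaussian lasso treats photometry noise as white; correlated noise is
  only partly absorbed by trial-blocked cross-validation.
* The circuit model is a two-input rate abstraction — no conductances,
  dynamics, or fitted parameters.
* Conclusions from synthetic data validate the *pipeline*, not the biology:
  the generator produces exactly the signal family the models assume.
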