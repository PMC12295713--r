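---
title: "Modelling platelet calcium time curves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling platelet calcium time curves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Blood platelets respond to agonists — collagen and collagen-related
peptide (CRP) acting through the GPVI receptor, thrombin through PAR1/4 —
with a rise in cytosolic free calcium, `[Ca2+]i`, measured in nM with the
ratiometric dye Fura-2 over a 540 s record. The shape and size of that
rise depend on the agonist and its dose, and on pharmacological
manipulations of the calcium machinery: chelating extracellular calcium
with EGTA (versus adding CaCl2) removes store-operated entry through
STIM1–Orai1; apyrase plus indomethacin ("AI") removes autocrine
ADP/thromboxane feedback; thapsigargin blocks the SERCA pumps that refill
the stores, which under CaCl2 converts responses into sustained rises.

`platecal` models such curve collections with three complementary,
data-driven tools:

* a **magnitude network** — a single-hidden-layer perceptron with
  rectified-linear nodes predicting `log10(max − min)` of a curve (its nM
  range) from the experimental condition;
* a **trend network** — a closed-loop NARX recurrent network (nonlinear
  autoregressive with exogenous inputs) predicting the 0–1 min–max-scaled
  curve shape one second at a time from its own delayed outputs plus the
  condition; and
* **PLS regression** — mean-centered single-response partial least squares
  mapping the condition variables to four scalar curve characteristics,
  read through its loading weights.

The combined networks reconstruct nanomolar curves
(`trend × magnitude`), enabling a one-at-a-time (OAT) sensitivity sweep
over low agonist doses under all inhibitor combinations.

## The experimental design encoding

The default design (`build_design_matrix()`) enumerates 72 conditions:
eight vehicle/thapsigargin controls covering all `2^3` inhibitor-flag
combinations (experiments 1–8), collagen at 1, 3, 10, 30 µg/mL
(experiments 9–32), CRP at 1, 10 µg/mL (33–48) and thrombin at 0.3, 1,
3, 10 nM (49–72). Collagen and thrombin cross six flag combinations per
dose (thapsigargin crossed with EGTA only), CRP all eight. Known anchors
are respected — experiment 36 is CRP + EGTA, 42 is CRP + AI, and the
thrombin-heavy test conditions 63, 67, 70 and 72 sit in the thrombin
block — but the enumeration is a documented canonical fixture, not a
claim that any particular laboratory plate looked exactly like this.

Conditions are scaled for modelling: flags to {0, 1}, agonist doses
linearly to [0, 10] with the stated maximum mapping to exactly 10
(`scale_conditions()`). The six channels are expanded to 27 network
inputs: linear terms, squares, and the fifteen pairwise products in fixed
lexicographic order (`expand_features()`). The separate 16-condition
drug-validation design (`build_design_matrix(include_drug_block = TRUE)`)
crosses maximal agonist or thapsigargin-only stimulation with EGTA/CaCl2
and the calcium-entry-blocking drug 2APB; the drug flag is used only by
the PLS analysis, never by the networks.

### Train/validation/test split

`assign_splits()` defaults to 58 training, 7 validation and 7 test
curves. The test set is thrombin-heavy (including experiments 63, 67, 70,
72); validation spans all three agonists (including the CRP anchors 36
and 42). Both hold-out sets contain only agonist conditions with a clear
response: a synthetic vehicle control is pure measurement noise after
min–max scaling, so its per-curve trend R² is structurally near zero
whatever the model — holding such curves out would measure the noise
floor, not the model. For the same reason hold-outs avoid conditions
whose noiseless response (≈ 2 nM for 1 µg/mL collagen under EGTA) sits
below the 3 nM noise floor. Controls and near-floor conditions remain in
the training set.

## The synthetic-data generator

No public single-donor dataset accompanies the curve descriptions, so
`generate_dataset()` provides a phenomenological stand-in with the same
statistical structure. Each condition's noiseless curve is

```
baseline + A * r(t) * d(t) + thapsigargin term,
r(t) = 1 − exp(−max(0, t − lag)/tau_rise)
d(t) = s_end + (1 − s_end) * exp(−max(0, t − t_peak)/tau_decay)
```

with amplitude `A = amp_max · Hill(dose; ec50, hill) · (EGTA? 0.3 : 1) ·
(AI? 0.7 : 1) · (drug? 0.3 : 1)` and `t_peak = lag + 3·tau_rise`. Under
thapsigargin with CaCl2 the agonist decay is removed (`s_end → 1`) and a
slow sustained term (250 nM before modifiers) is added. Defaults encode
the qualitative phenomenology: transient thrombin curves
(`s_end = 0.35`, fast rise), monotone collagen/CRP curves
(`s_end ≈ 0.9–0.95`), EGTA lowering amplitudes to 0.3× (within the
"up to four times" ratio between CaCl2 and EGTA), AI to 0.7×, and the
entry-blocking drug acting like EGTA. Baseline is 60 nM and noise is
additive i.i.d. Gaussian with SD 3 nM, truncated at 0 nM; calibrated
ratiometric traces are smooth with small jitter, and this noise model is
deliberately simple. Raw sampling is 2 s for thrombin and 4 s otherwise,
over 0–540 s.

What the generator does **not** emulate: biphasic CRP second waves,
donor-to-donor variability, baseline drift, or any mechanistic
SOCE/SERCA kinetics — the networks are data-driven, so the fixture only
needs the statistical structure, not mechanism. Passing tests on this
generator therefore demonstrate that the pipeline recovers structure a
real dataset of this shape would carry; they do not certify performance
on any particular donor's platelets.

## Preprocessing

Raw curves are linearly resampled to 1 s steps over 0–540 s (541 points;
no extrapolation outside the sampled range unless explicitly clamped),
smoothed with a Savitzky–Golay filter, and min–max scaled per time
series with the back-transform constants retained. The filter window and
order are not dictated by the source material; the defaults (11 s
window, cubic) preserve the fastest thrombin transients at 1 Hz while
suppressing sampling noise, and both are configurable. Flat curves
(range below 1e-6 nM, e.g. a zero-noise vehicle control) are rejected
with the offending experiment id rather than silently scaled.

## Scalar curve characteristics

`compute_scalar_features()` reports magnitude (max − min, nM), `tmax`
(time of first maximum / 540), `ylast` (terminal value scaled by the
magnitude) and `absdev` — the mean absolute deviation of the scaled
curve from the straight chord joining its first and last points, over
all 541 points. The chord convention makes `absdev` exactly 0 for linear
curves; absolute rather than signed deviations are used, so symmetric
over- and undershoots do not cancel. Ties at the maximum resolve to the
earliest time. On a flat curve the shape features are undefined and are
returned as flagged `NA`s, never silent zeros.

## The magnitude network

A single hidden layer of 1–10 rectifier nodes maps the 27 features to
`log10(max − min)`; the log target makes the mean-squared-error cost
weight high- and low-magnitude curves comparably. Training is damped
least squares (Levenberg–Marquardt via `minpack.lm`) with an analytic
Jacobian and subgradient 0 at the rectifier kink. Two numerical details
matter:

* a Tikhonov tail of `sqrt(1e-8) · theta` is appended to the residual
  vector so the residual count never falls below the parameter count
  (a requirement of the LM routine); at this weight it is numerically
  irrelevant to the fit;
* inputs are min–max normalised to [−1, 1] with constants fitted on the
  training rows and stored in the model, and training is stopped early
  when the validation cost has not improved for six consecutive
  three-iteration optimiser chunks, keeping the weights with the best
  validation cost seen. Both mirror the default behaviour of the
  neural-network tooling this estimator emulates.

Each restart draws its node count uniformly from 1–10 and fresh
fan-in-scaled uniform(−0.5, 0.5) weights. The restart with minimal
validation MSE is the champion (ties: fewer nodes, then restart order).
By default the returned predictor takes the member-wise *median* of the
best-by-validation restarts in log space (`fit_mlp` itself defaults to
100 restarts with a 10-member committee; the pipeline uses 200 and 20):
a seven-curve validation set can rank overall fit quality but cannot
police extrapolation at condition-space corners that neither training
nor validation contains, where an individual rectifier network can be
wildly — and asymmetrically — wrong. The median over a committee is
robust to those heavy-tailed member errors where a mean is not, while
leaving interpolation essentially unchanged. `ensemble = 1` restores
single-network behaviour, and the champion with its selection record is
always retained. Relatedly, the quadratic dose features let the fitted surface
bend downward again beyond the largest training dose; the surface is
trustworthy over the interior of the training hull (in particular the
low-dose range the OAT sweep probes), not beyond it.

## The trend network

The trend network predicts the scaled curve one second at a time. Eight
feedback taps read the model's own output 1, 3, 6, 10, 15, 21, 28 and
36 s before the current step (lags are sample indices at 1 Hz; taps
before the record start are 0, the pre-stimulation steady state). The
taps feed all three tanh hidden layers, as the layered recurrence is
written; a configuration restricting them to layer 1 was considered and
rejected as a needless second code path (the extra weights are free to
be zero). The output layer is linear, not tanh: min–max targets attain
exactly 0 and 1, which tanh cannot reach. Simulated trends may therefore
overshoot [0, 1] slightly; the combined predictor clips and records the
clipped fraction, never silently.

Training minimises the mean squared error of the *closed-loop rollout* —
the honest objective, since prediction-time simulation is closed-loop —
but that objective is poorly conditioned from a random start. The
default schedule therefore stages the optimisation:

1. **series-parallel warm start** (teacher forcing): the lag taps read
   the target curve, collapsing the recurrence into a feedforward
   regression over all time steps, optimised by L-BFGS with an analytic
   gradient (every second time step; the stride is configurable);
2. **truncated rollout segments**: 61 s closed-loop windows whose
   out-of-window taps read the target history, batched across all curves
   and window starts — rollout-consistent gradients at a fraction of the
   sequential depth;
3. **full closed-loop fine-tuning** with backpropagation through time.

The rollout recursion and its BPTT gradient are compiled
(RcppArmadillo); restarts whose cost diverges are discarded and counted
in the training record.

The architecture search samples without replacement from the
19 × 19 × 19 grid of layer sizes 2–20 (6859 candidates; the full grid
and 100 restarts remain available by configuration for cluster-scale
runs). Each candidate is screened with five cheaply-trained restarts
(warm-start phases only) and ranked by mean closed-loop trend R² on the
validation curves, ties towards fewer parameters. The winning
architecture is then retrained at full depth — eight restarts through
all three phases, with a 600-iteration closed-loop budget. By default
the returned trend predictor is the *point-wise median* of the member
networks' simulated curves, members ordered by validation trend R²
(`ensemble = 1` returns the single best-by-validation network).
Closed-loop training is non-convex, and an individual rollout
occasionally settles on a qualitatively wrong asymptote for a held-out
condition; across restarts those failures are idiosyncratic, so the
median trajectory suppresses them while tracking the consensus shape.
Screening cheaply and spending the closed-loop budget only on the
winner keeps the whole search within a desk-scale compute budget; the
selection-by-validation principle is applied at both stages.

## Combined prediction and the OAT sweep

`predict_nm_curve()` reconstructs `offset + clip(trend) × magnitude`.
For de novo prediction the offset is 0: the networks model the response
range above resting level, not absolute resting calcium. The OAT sweep
(`oat_sweep()`) varies one agonist at a time over 1–10% of its maximal
training concentration (30 µg/mL collagen, 10 µg/mL CRP, 10 nM thrombin)
under all eight inhibitor-flag combinations, everything else at
baseline, and tabulates the four scalar characteristics of each
predicted curve (magnitude on a log10 scale). The sweep reproduces the
*procedure*; with synthetic training data its numeric patterns describe
the generator, not any particular donor.

## PLS regression

`fit_pls()` is single-response NIPALS (PLS1): each component's loading
weights are proportional to the X–y covariance of the deflated data,
scores are orthogonal by construction, and with as many components as
variables the prediction coincides with ordinary least squares on
full-rank data (a tested limit). Variables enter on their stated scales
([0, 1] flags, [0, 10] doses), mean-centered only — no unit-variance
scaling — so loading weights are read on those scales; this matches how
the condition variables were already normalised by design, and is
configurable by pre-scaling X. "Loadings" reported by `pls_loadings()`
are the loading weights `a_ji` (the interpreted quantities), with the
X-loadings `p_ji` available by option. Models for the four
characteristics use two components by default; the per-component
explained variance of the response is reported so users can judge that
choice, which is a configuration value, not a hard-coded truth. The
58/14 train/test split reuses the curve-level split (validation and test
merged as the PLS test set). If a planted response is exhausted before
the requested number of components (exactly collinear fixtures), the
model truncates to the components actually extracted.

The drug-augmented analysis (`drug_augmented_pls()`) fits the
seven-variable models on the 16-condition design and reports the
Euclidean distance from the drug's loading to every other variable's
loading in the component-1/2 plane; an entry-blocking drug is expected
to land nearest EGTA, and on the generator fixture (where the drug
applies the EGTA amplitude factor) it does.

## Numerical choices and degenerate inputs

* Degeneracy threshold for flat curves: 1e-6 nM on the range.
* Ties at the curve maximum: earliest time.
* Feature order: linear, squares, lexicographic cross terms — fixed for
  reproducible model files.
* Weight initialisation: fan-in-scaled uniform(−0.5, 0.5), seeded per
  restart; every fitting function is bit-reproducible given its seed and
  restores the caller's RNG state.
* The discrete 541-point mean |deviation| of the scaled parabola
  `4u(1−u)` is 0.66543, approaching the integral 2/3 as the grid refines;
  tests freeze the exact discrete value.
* Two-component PLS recovers a planted two-coefficient response exactly
  only when the centered design columns are orthogonal (the coefficient
  vector must lie in the order-2 Krylov space); general full-rank designs
  are covered by the full-component OLS limit.

## Problem sizes and budgets

The default desk-scale configuration (`pipeline_config()`) — chosen as
the package's reference study conditions — uses the 72-condition design
with 3 nM noise, a 30-architecture × 5-restart trend-network search
with the staged warm start (an 8-restart, 100/200/600-iteration final
retrain of the winner), and 200 magnitude-network restarts with a
20-member median committee. A full `run_pipeline()` takes roughly ten
minutes on one CPU. The cluster-scale settings of the emulated workflow
(≈ 7000 architectures × 100 restarts) are reachable through the same
configuration object.

## Known limitations

* The generator is phenomenological; none of its parameters are fitted
  to published curves, and users with real calibrated data should load
  it via `read_curves()` and skip the generator entirely.
* Trend-network training is non-convex; different master seeds give
  different held-out mean R² (roughly 0.5–0.7 for a single network,
  raised and stabilised by the median ensemble), with transient
  thrombin-like curves consistently the hardest — the same qualitative
  failure mode reported for the real data.
* The magnitude surface should not be read outside the training dose
  hull.
* PLS is linear by design: it reads effect directions, not the
  nonlinear dose–response detail the networks capture.
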