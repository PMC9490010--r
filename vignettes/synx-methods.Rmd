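---
title: "EMG-driven model calibration with synergy extrapolation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG-driven model calibration with synergy extrapolation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synx)
```

## The problem

EMG-driven musculoskeletal models predict net joint moments from measured
muscle excitations through activation dynamics, a Hill-type muscle model
and musculoskeletal geometry. Calibrating such a model means adjusting its
activation-dynamics and muscle-tendon parameters until the predicted
moments track inverse-dynamics (ID) moments over a set of gait cycles. In
practice, some muscles important to the solution — most prominently the
deep hip flexors iliacus and psoas — cannot be measured with surface EMG.
Synergy extrapolation (SynX) closes that gap: because muscle excitations
during gait are well described by a small number of synergies, an
unmeasured muscle's excitation can be represented as a linear combination
of the synergy excitations extracted from the *measured* muscles, and the
combination weights can be estimated *during* calibration from the same
joint-moment tracking objective.

`synx` implements this whole chain: gait-cycle time normalisation, EMG
processing, PCA-based muscle synergy analysis with trial-, speed- and
subject-specific concatenation, the EMG-driven forward chain, the
multi-term calibration objective, validation on held-out trials, and a
synthetic-data generator with full ground truth so that every stage can be
verified quantitatively without any external data.

## Data model and time grid

A gait cycle lives on a 121-frame grid: 101 frames spanning heel-strike
(0%) to the next ipsilateral heel-strike (100%), preceded by 20 pre-frames
at the same spacing. The pre-frames exist so that an electromechanical
delay of up to 100 ms can be applied causally; with typical cycle
durations above one second, 20 frames of pre-window comfortably cover it.
Resampling onto this grid (`resample_to_cycle()`) interpolates linearly
(exact for the piecewise-linear fixtures we test with; the choice is a
package decision — the convention itself does not prescribe an
interpolant) and refuses to extrapolate: the source recording must contain
the pre-window.

EMG processing follows the standard recipe: zero-phase high-pass at 40 Hz,
demeaning, full-wave rectification, zero-phase low-pass at `3.5/tf` Hz
(with `tf` the cycle period), then per-channel normalisation to the
maximum over all cycles. The filters are 4th-order Butterworth applied
forward–backward; zero-phase filtering is deliberate, since any filter
group delay would be absorbed into — and corrupt — the calibrated
electromechanical delay. Small negative values after the final low-pass
are clipped to zero because the activation dynamics expects excitations in
[0, 1].

## Muscle synergy analysis

Measured excitations are decomposed by PCA as `E = Wm Hm + mu + eps`,
where `Wm` holds the synergy excitations (component scores), `Hm` the
synergy vector weights (loadings) and `mu` the channel means. How matrices
are concatenated before PCA encodes an assumption about weight
variability: one decomposition per trial (121 frames each), per speed
(605 frames for five cycles), or one for the whole subject (1210 frames
for ten cycles). Variance accounted for is computed in the uncentred,
pooled form `VAF = 100 (1 - ||E - Ehat||_F^2 / ||E||_F^2)` — the
muscle-synergy literature convention, which makes a 95% threshold
meaningful for non-negative excitation signals. Component signs are fixed
by making each component's largest-magnitude loading positive, so results
are reproducible across platforms.

Two choices the convention leaves open were resolved as follows:

* **VAF pooling.** VAF is pooled over the whole matrix (Frobenius norms)
  rather than averaged per channel.
* **Score normalisation.** Inside the calibration, each synergy
  excitation column is divided by its group-level standard deviation
  (degenerate components are floored so numerical-noise directions cannot
  be amplified). Without this, weights attached to low-variance
  components have curvature orders of magnitude smaller than those of the
  leading component and every optimizer tested stalled; with it, all
  weight directions act on a common scale. The stored decompositions keep
  raw scores; normalisation is part of the optimisation parameterisation
  only.

## The EMG-driven forward chain

Per muscle, excitation is scaled by `semg` (bounds [0.05, 1], reflecting
that true maxima are likely higher than observed), clamped to [0, 1],
delayed by `d` seconds (`d` is bounded by 0.1 s), and passed through the
first-order activation ODE `du/dt = (c1 e(t-d) + c2)(e(t-d) - u)` with
`c1 = 1/tau_act - 1/tau_dact`, `c2 = 1/tau_dact` and the deactivation
constant tied as `tau_dact = 4 tau_act`. The ODE is integrated with the
exact update for piecewise-constant excitation,
`u[k+1] = e[k] + (u[k] - e[k]) exp(-(c1 e[k] + c2) dt)`, which is
unconditionally stable and exact under the step-signal model. Neural
activation then passes through the nonlinearity
`a = (1 - c3) u + c3 [g1 g2^((u+g3)^g4) + g5 + 1]`; the printed form of
that bracket is ambiguous in the literature, so the package treats it as a
configurable monotone map with endpoint constraints `a(0) = 0`,
`a(1) = 1`. The shipped constants (`g1 = 1/9, g2 = 10, g3 = 0, g4 = 2,
g5 = -10/9`) give the convex map `(10^(u^2) - 1)/9`.

Force follows the rigid-tendon Hill model
`F = Fmax (a fl(l) fv(v) + fp(l)) cos(alpha)` with normalised fiber
kinematics `l = (lMT - lsT)/loM`, `v = vMT/(10 loM)` (shortening
negative; maximum shortening velocity ten optimal fiber lengths per
second). The curve family is a registry — any `fl`/`fv`/`fp` functions
can be swapped in — with defaults: Gaussian active force–length
`exp(-(l-1)^2/0.45)`, a Hill hyperbola on the concentric side
(`fv(0) = 1`, `fv(-1) = 0`) continued C1-smoothly into a saturating
eccentric branch with asymptote 1.4, and an exponential passive curve
that is zero at or below optimal length. Net joint moments are
`M = sum_m F_m r_m`, with moment arms `r = -d(lMT)/d(theta)`.

Geometry is either analytic (the planar-leg fixture) or a fitted
polynomial surrogate of `lMT(theta)` per muscle; moment arms and
muscle-tendon velocities are always obtained by differentiating the
length model (`vMT = -sum_d r_d thetadot_d`), never fitted independently,
which keeps the three quantities mutually consistent by construction.

## The calibration problem

Three cases are supported, distinguished by which design variables exist:

* **Params + SynX + Res** — activation-dynamics parameters (`semg`, `d`,
  `tau_act`, `c3`) and length scale factors (`scale_lo`, `scale_ls` in
  [0.6, 1.4]) per muscle, plus unmeasured weights `(HSynX, muSynX)` and
  residual weights `(Hres, mures)`. Four cost terms: moment tracking with
  residuals included, moment tracking without residuals, unmeasured
  activation magnitude, residual activation magnitude.
* **Params + SynX** — as above without the residual side (two terms).
* **Params** — parameters only, full excitation set, moment tracking
  only.

Residual excitations are a synergy-structured correction added to the
*measured* excitations; they are allowed to be negative, and both the
residual-included and residual-free moments enter the cost so that
residuals absorb what they should (noise, model error) without dragging
the calibrated parameters away from the residual-free solution. Each
weight side may use its own category (trial/speed/subject); each side
always reconstructs from the synergy excitations of its own category's
decomposition.

Every term is a sum of squares normalised by a maximum allowable
deviation (MAD). The package's defaults come from its own sensitivity
sweep on noiseless recovery experiments: `mad_mom = mad_mom_res = 0.5`
N·m and `mad_act_synx = mad_act_res = 1.0` activation units. Only the
ratio matters; this ratio makes moment tracking dominate, so the
activation-magnitude terms act as weak priors that resolve redundancy and
curb overestimation without visibly biasing the tracked solution. In the
sweep, moment MADs of 1–2 N·m left visible shrinkage bias in recovered
unmeasured excitations, while 0.1–0.25 N·m destabilised the optimisation
into spurious basins; 0.5 N·m was reliable on both counts. An auxiliary
penalty (`Jpen`, scale 0.1) pushes constructed excitations that leave
[0, 1] back into range: the muscle model clamps its input, so out-of-range
values are otherwise cost-invariant and can trap the optimizer on a flat
region (we observed unmeasured excitations pinned at -2 without it). The
penalty is exactly zero for any in-range solution, so it cannot bias a
feasible optimum.

### Solving it

The cost is a sum of squares, so the default solver is
Levenberg–Marquardt on the stacked residual vector. Box bounds are
enforced smoothly through a sine transform (shifted by one period so the
solver's initial trust region, which scales with the norm of the starting
point, does not collapse at a mid-bounds start). The finite-difference
Jacobian exploits problem structure: a trial-specific weight only
influences its own trial, a speed-specific weight only its speed's
trials, so most Jacobian columns need only a fraction of the trials
re-evaluated. When model parameters are frozen and all weight categories
are within-speed, the problem separates exactly into independent
per-speed problems, which are solved separately. Initial guesses are
mid-bounds for parameters and zero for weights, with unmeasured average
values started at the mean measured excitation level. A bounded
quasi-Newton fallback (`optimizer = "lbfgsb"`) is retained.

Pure parameter calibration has a known pathology: redundant muscles
crossing the same joint can compensate each other's length scale factors,
creating local minima where the moment error is tiny but several scale
factors are a few percent off. Neither whole-vector multistart,
per-muscle coordinate polish, soft-eigendirection line searches, nor a
force-length-width homotopy escaped these basins reliably in our
experiments. What does work is seeded basin hopping over the scale-factor
subspace of one DOF's muscle group at a time (groups read off the
moment-arm structure): perturb that group's scales, re-converge, keep the
result if better, and stop as soon as the cost is numerically zero —
which on noiseless data identifies the global optimum unambiguously. With
this phase enabled (the default for the `params` case) the calibration
recovered the true scale factors to numerical precision on every seed we
tested.

### Validation

Trial-specific weights cannot transfer to new trials; speed- and
subject-specific ones can. `predict()` on a fit obtains measured synergy
excitations for the *new* trials by projecting their measured
excitations onto the calibration decomposition's basis (the loadings and
channel means of the trial's group under the calibrated category),
normalised exactly as during calibration, then combines them with the
*fixed* calibrated weights and parameters and reports per-trial moment
tracking metrics. Projection — rather than re-running PCA on the new
trials — is essential: a fresh PCA carries arbitrary component signs
and, when adjacent component variances are close, arbitrary rotations,
which would silently detach the fixed weights from the components they
were calibrated against.

## The synthetic testbed

The generator builds a ground-truth twin of a two-speed treadmill
protocol: 5 cycles per speed at a self-selected (~1.4 s cycle) and a
fastest-comfortable (~1.15 s) speed, 12 muscles over 4 DOFs (hip
flexion/extension, hip add/abduction, knee flexion, ankle
plantar/dorsiflexion), 5 generating synergies. Synergy excitations are
raised-cosine bumps at staggered gait phases with distinct amplitudes and
widths, so the PCA variance spectrum is well separated but no component
is negligible; weights are non-negative and sparse-ish (each muscle loads
mainly on one synergy), varying per trial, per speed, or not at all
according to the configured weight variability. Excitations are
normalised per channel to a maximum of 1 over all cycles — exactly what
max-normalised processed EMG looks like — which preserves the exact
rank-5 structure about the mean when noise is zero. Joint angles are
three-harmonic periodic curves (real gait kinematics carry substantial
higher-harmonic content, and the wider fiber-length excursions make the
length parameters identifiable from moments). "Experimental" moments are
forward-computed at true parameters drawn from realistic ranges
(`semg` 0.75–0.95, delays 10–50 ms, `tau_act` 15–35 ms, `c3` 0.05–0.25,
length scales within ~8% of nominal), with optional additive Gaussian
noise on excitations and moments.

Two fixture choices deserve explanation. The two deep hip flexors carry
opposite-signed hip add/abduction moment arms and well-separated sagittal
moment-arm phases: when both are held out simultaneously, the split of
the shared hip flexion moment between them is identifiable only if their
joint-moment signatures are linearly independent, and a single shared hip
DOF makes the pair nearly collinear (recovery then collapses into a basin
where one muscle carries everything). Full musculoskeletal models give
the hip three DOFs for the same reason. Second, every joint has an
antagonist, and there are more muscles than DOFs, so the moment-matching
problem retains the redundancy that makes the SynX regularisation terms
meaningful.

What the generator does **not** emulate: measurement artefacts and
crosstalk in EMG, soft-tissue artefact in kinematics, model-form error in
the geometry (the fixture geometry used for generation is the one used
for calibration), and pathological synergy merging (a lower `p*` can be
configured, but no claim about stroke-specific structure is made).
Passing recovery tests on this data therefore demonstrates the
correctness and conditioning of the estimation machinery — not that the
model family captures real muscle physiology.

## Numerical choices and degenerate inputs

* All randomness is seed-controlled; generator and calibration are
  deterministic given their seeds.
* PCA with `p` equal to the matrix rank reproduces the input to 1e-10;
  degenerate (zero-variance) components are kept but floored in the
  normalised parameterisation so they cannot inject noise.
* All-zero EMG channels are left at zero with a warning during
  normalisation (division guard); an all-zero reference matrix makes VAF
  undefined and is an error.
* Non-finite model outputs during optimisation yield a large finite
  penalty residual rather than an error, so a line search can back off.
* Excitations are clamped to [0, 1] only at the muscle-model boundary;
  the unclamped values feed the magnitude and range-penalty terms.
* The correlation strength categories are left-open intervals with
  boundaries honoured exactly (0.35 is "moderate", 0.9 is "strong"); the
  upper category is `r > 0.9`.

## Problem sizes used in the shipped experiments

The recovery, residual-benefit and validation experiments in the test
suite and in `scripts/acceptance.R` use the generator defaults above (10
calibration cycles of 121 frames, 12 muscles, 2 held-out, 6 synergies in
the SynX cases), which we consider the smallest configuration that
preserves the redundancy structure of a full lower-limb calibration.
A full `params_synx_res` calibration at this size has 352 design
variables and completes in about a minute; weights-only recovery and the
pure parameter case typically converge in tens of seconds.
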