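---
title: "A V1 population model linking tilt repulsion and contrast sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A V1 population model linking tilt repulsion and contrast sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltcsf)
```

## The scientific problem

Two of the most informative monocular psychophysical measures — the
centre–surround tilt illusion and the contrast sensitivity function (CSF) —
are usually analysed with unrelated descriptive curves, one logistic per
condition. Yet both are thought to arise in the same cortical circuitry: a
local population of orientation-, SF- and contrast-tuned neurons receiving
lateral inhibition from its spatial surround. This package implements a
two-layer conductance-based population model in which a *single* inhibition
parameter shapes both measures, so that fitting the tilt data first and the
contrast data second dissects behavioural differences (for instance between
amblyopic, fellow and neurotypical eyes) into three interpretable network
characteristics:

* `I_inh` — mean surround-to-centre inhibitory strength per surrounding
  hypercolumn (dimensionless conductance scale; total surround drive is
  `n_s * I_inh` with `n_s = 6`);
* `sigma_theta` — orientation tuning width of the local population
  (degrees); and
* `c_min` — the smallest contrast semi-saturation constant across the
  population (dimensionless contrast), i.e. the best neuronal contrast
  sensitivity, with its SF dependence parameterized by `(a, b)`.

## Model structure and assumptions

First-layer ("simple-cell") rates are separable products of a wrapped
Gaussian in orientation, a log-Gaussian in SF, and a hyperbolic-ratio
contrast response with exponent `n = 2`, scaled by amplitude `A = 2`. The
contrast term is normalized by `1 + c_k^n` so every neuron reaches exactly
1 at full contrast; as a consequence the semi-saturation constant no longer
marks the half-response point, and `half_amplitude_constant()` recomputes
the contrast of half-maximal normalized response.

Second-layer neurons receive iso-feature Gaussian-weighted excitation from
their own hypercolumn and inhibition from a uniform surround, with feed-
forward widths fixed at half the population widths (the centre/surround
width entanglement). The membrane equation is solved at its steady state
`v = (v_e g_e + v_i g_i)/(1 + g_e + g_i)` with `v_e = 14/3`, `v_i = -2/3`,
and rates are `max(0, v - 1)`. The model is purely feed-forward: no
recurrence, no dynamics beyond the consistency check that forward
integration of the membrane equation reaches the closed-form fixed point
(tested against `deSolve` to 1e-8).

Perceived orientation is the vector average of the centre-hypercolumn
rates. Orientation is an axial variable with period 180°, so the resultant
is computed on doubled angles and its argument halved — the only
rotation-equivariant definition of a "vector average" for orientations.
Decoding weights are the post-rectification firing rates, not voltages and
not baseline-subtracted rates: decoding "activity" means spikes, and the
rectified model has no spontaneous baseline to subtract.

Contrast detection at SF `f` is carried by the channel with the smallest
semi-saturation constant at that SF. Its envelope
`c_k_min(f) = c_min ((ab)^a e^-a)/(f^a e^(-f/b))` has its minimum `c_min`
exactly at `f = a b`. Detection follows two-interval signal detection
theory: `d' = (R_signal - R_blank)/sqrt(Var(R_signal) + Var(R_blank))`,
`P_th = 2(pnorm(d'/sqrt(2)) - 0.5)`, embedded between the guess floor
`gamma` and the lapse ceiling `1 - lambda`.

## Design choices that were genuinely open

**Variance of the decision variable.** The model specifies rates, not
spike-count distributions, so `Var(R)` had to be chosen. We use
Poisson-like variance with a spontaneous floor, `Var(R) = R + r0`, which
keeps the blank interval well defined. The floor's value matters: the
decision neuron's rate at full contrast is at most about 2.1 under the
fixed parameter set, and with `r0 = 1` the d' needed to reach the
psychometric midpoint requires a rate of about 1.9 — attainable only when
inhibition is weaker than `I_inh` of about 0.01, i.e. for observers with a
nearly invisible tilt illusion. That would make the model's central
coupling between the two measures empirically empty. We therefore default
to `r0 = 0.01`, a small regularizing floor under which detection remains
possible up to `I_inh` of about 0.1, the same range that produces tilt
biases of one to eight degrees. The floor is exposed as `r0` in all
relevant functions and in the `r0_floor` configuration key.

**SF coupling kernel.** The tuning-width rule
`sigma_SF(f) = exp(-(f - 2)/0.2)` decays extremely fast: at 4 c/d the
width is already ~5e-5 octaves, far below the quarter-octave population
sampling, so a discrete sum over the SF grid is numerically meaningless
there. The feed-forward coupling along SF is therefore computed as the
analytic Gaussian-convolution kernel (`sf_coupling()`), the dense-grid
limit of the numeric sum; at the matched SF, with the half-width
entanglement, its value is `1/sqrt(1.25)` independent of the width, which
makes the detection pathway insensitive to the rule's steepness. The
orientation dimension keeps both forms: the closed-form expression and the
explicit grid summation agree to better than 1e-6 relative error over
random parameter draws (tested), with the closed form used in fitting for
speed.

**Feed-forward weight normalization.** Weights are area-normalized on the
input grid, so the total synaptic drive does not depend on how finely the
input population is sampled; this is what makes the closed form and the
grid summation agree exactly rather than up to a resolution-dependent
scale.

**Grid edges and wrapping.** The orientation grid spans −90° to +88°
inclusive in 2° steps (one full period, no duplicate at +90°); decoded
angles are reported in (−90°, +90°]. Wrapped Gaussians sum wraps
k ∈ {−2, …, 2}; the truncation error is below 1e-12 for widths up to 40°.
The grid is closed under negation modulo 180°, which is why the
antisymmetry of the bias curve holds to machine precision rather than only
to grid resolution.

**Three-key data at fitting time.** Undecided detection trials and
not-seen tilt trials are removed from the Bernoulli likelihood
(`drop_unforced_trials()`); their information enters through the
data-derived guess rate `gamma = max(0, (1 - p3/0.7)/2)` and through the
pooled suppression proportions. The *staircase-time* rule is different and
lives in the simulator: an undecided or not-seen press steps the staircase
as a random coin flip. Keeping the two rules separate mirrors the
experimental protocol.

**"Bayesian" fitting.** All fits are bounded maximum likelihood (MAP with
flat box priors) from deterministic multi-starts: the downstream analysis
only ever uses point estimates and −log(ML), so posterior machinery would
add nothing. Optimization bounds are generous and configurable:
`I_inh ∈ [0, 5]`, `sigma_theta ∈ [2°, 60°]`, `c_min ∈ [1e-4, 1]`,
`a ∈ [0.1, 5]`, `b ∈ [0.2, 32] c/d`; stage 1 starts from a 3 × 3 grid over
`(I_inh, sigma_theta)`. Parameter regions where inhibition silences the
entire population (undefined decode) receive a large penalty rather than
an error. Likelihoods are order-invariant sums, so permuting trials leaves
the fit unchanged to 1e-9 (tested).

**Model scope over surround orientations.** The model stage fits only
±15° and ±30°: the indirect tilt effect at ±75° arises beyond this
circuit, and the model makes no prediction for it. The descriptive per-SO
fits include all surrounds. Whether surround hypercolumns inhibit each
other is left unspecified by the feed-forward architecture; only
centre-hypercolumn outputs are computed, which is all the predictions use.

## Tunable parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `I_inh` | — | fitted | surround inhibition per hypercolumn |
| `sigma_theta` | degrees | fitted | population orientation tuning width |
| `threshold_sigma` | degrees | fitted | discrimination spread, one per SF |
| `c_min`, `a`, `b` | —, —, c/d | fitted | neuronal sensitivity envelope |
| `gamma` | — | from `p3` | guess floor, never fitted |
| `lambda` | — | 0.01 | lapse ceiling |
| `r0` | rate | 0.01 | variance floor of the decision stage |
| `prune_above` | — | 1000 | semi-saturation pruning bound |

The psychometric spread convention is shared everywhere: the logistic
slope factor is `log(21/4)`, so one spread unit above the midpoint sits at
exactly 21/25 = 84% of the floor-to-ceiling range, and `2 sigma` spans
16–84%.

## What the simulated observers emulate — and what they do not

The generator reproduces the protocol exactly: 165 detection trials
(15 per SF at eleven SFs from 0.71 to 22.63 c/d) with per-SF weighted
up-down staircases in log10 contrast (down/up steps 4.5/8 or 1.5/7 times
log10(1.1) on alternating SFs, the down step tripled for the first four
trials, published starting contrasts); and 420 tilt trials (7 surrounds ×
2 staircases × 30 trials) with 2/5 and 5/2 degree staircases starting
10° on the opposite side of the convergence point, strictly alternated
within each surround (the protocol does not specify the interleaving
order; strict alternation is the simplest reproducible choice).

Observers can generate responses from the network model itself (mode
`"v1"`, one shared `I_inh` — the coupling under test) or from the
descriptive curves (mode `"adhoc"`, useful for oracle-style recovery
checks because the fitted family then nests the truth). Third-key usage is
modelled as a contrast-independent propensity, which makes the
`gamma(p3)` calibration hold exactly by construction; real observers press
the third key more at low contrast, a feature deliberately not emulated —
passing recovery tests therefore shows the estimator is consistent for the
stated generative model, not that the calibration is exact for humans.
Not-seen responses follow a suppression profile peaking at iso-orientation
(Gaussian decay over SO, width 25° by default) and stronger at the high
SF. Reaction times, learning, fatigue and eye movements are not modelled.

Cohort regimes (`make_cohort()`) encode the phenomenology the model is
meant to dissect, chosen from the model's own operating range (tilt biases
of roughly 1.5–8° and peak sensitivities of roughly 60–250): amblyopic
eyes draw `sigma_theta` from 20–30° versus 12–19° for fellow/neurotypical
eyes, and `I_inh` from 0.03–0.09 versus 0.01–0.06; `c_min` varies around
0.005. Because stronger inhibition mechanically lowers the predicted CSF,
the generated low-SF sensitivity is negatively coupled to `I_inh` within
each group — the structure the pipeline is expected to recover.

## Numerical choices

* CSF threshold search: bisection on log10 contrast to 1e-4 log-units;
  the threshold is the contrast where the detection term crosses one half.
  If the midpoint is not reached at full contrast the SF is reported as
  not measurable (`NA`), and channels whose semi-saturation exceeds 1000
  are pruned (detection falls to the guess rate there).
* Degenerate decodes (all-zero or perfectly uniform rate profiles) raise
  an error at the user surface and a finite penalty inside likelihoods.
* Detection-surface fits run 16 deterministic starts (L-BFGS-B on log
  parameters, Nelder-Mead fallback); per-SO fits share one threshold per
  opposite-surround pair and flag any surround with fewer than 5 usable
  trials instead of fitting it.
* All sessions derive every random draw from one seed; identical seeds
  give byte-identical trial tables, and the full cohort pipeline is
  end-to-end deterministic (tested).

## Problem sizes used by the test suite

The suite exercises the estimators at the protocol's own session sizes
(165 and 420 trials), uses 10,000-trial weighted expected-data designs
(`virtual_tilt_trials()`) for noise-free self-consistency, 50-seed
staircase replications for the tuning-width recovery distribution, and a
12-observer cohort (4 per group) for the group-structure checks. These
sizes were chosen to match the measurement protocol being modelled while
keeping the default test run in the minutes range.

## Known limitations

* The detection stage's dynamic range is narrow: because the decision
  neuron's rate saturates near 2.1, the model's psychometric surface is
  shallower than typical empirical detection functions, and the
  descriptive logistic fit of model-generated data tends to compensate
  with large spreads. This is a property of the model class, not of the
  implementation.
* `(I_inh, sigma_theta)` are weakly identified when the illusion is small
  (biases well under a degree): the likelihood then has a flat ridge and
  single-session estimates of `sigma_theta` can wander; the recovery
  tests characterize this at realistic session sizes.
* The envelope parameters `(c_min, a, b)` trade off against each other in
  a single 165-trial session; group-level conclusions are robust, but
  single-session `c_min` values carry substantial uncertainty.
* The SF tuning-width rule is taken as stated even though its decay above
  a few c/d is faster than physiological reports; the matched-SF
  detection pathway is unaffected by it (see the kernel argument above).
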