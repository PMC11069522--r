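---
title: "Modelling gaze dwell on facial regions with zero-inflated Beta regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gaze dwell on facial regions with zero-inflated Beta regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zibgaze)
```

## The problem

When people rate impressions of a face (how extraverted, agreeable,
conscientious, neurotic or open the person looks), where they direct their
gaze varies systematically between observers, and part of that variation
tracks the observer's own personality. The data unit this package works with
is the *dwell weight* $G_n \in [0,1)$ of one 3-second viewing trial on one of
six facial regions $n$ (eyes, nose, mouth, eyebrows, glabella, forehead):
the Gaussian-smoothed, area-normalised share of gaze density the region
received. Two viewing conditions are contrasted: *free* viewing of the whole
face, and *restricted* viewing through a small circular aperture that follows
the cursor, which isolates deliberate, conscious exploration from the
reflexive component of free viewing.

Dwell weights have two features that rule out ordinary regression: many
trials never touch a given region at all (an exact zero with positive
probability), and the positive values live on the open unit interval. The
natural model is zero-inflated Beta (ZIB) regression.

## The model

For one (condition, impression item, region) cell, the weight of trial $m$
by participant $i$ on image $j$ is

$$G \sim \mathrm{ZIB}(q, a, b), \qquad
\mathrm{ZIB}(G \mid q,a,b) =
\begin{cases}
1-q & G = 0\\
q \cdot \mathrm{Beta}(G \mid a, b) & G > 0
\end{cases}$$

with a logistic regression for the probability of looking at the region at
all (the **Bernoulli part**, "was it observed?"),

$$q = \mathrm{logit}^{-1}\!\Big(\alpha^{bern} + \textstyle\sum_{k=1}^{5}
\beta^{bern}_k P_k + r^{subj(bern)}_i + r^{pic(bern)}_j\Big),$$

and a Beta regression with mean $\mu$ and precision $\phi$ for how much it
was observed (the **Beta part**), using the mean/precision parameterisation
$a = \phi\mu$, $b = \phi(1-\mu)$:

$$\mu = \mathrm{logit}^{-1}\!\Big(\alpha^{Beta} + \textstyle\sum_{k=1}^{5}
\beta^{Beta}_k P_k + r^{subj(Beta)}_i + r^{pic(Beta)}_j\Big).$$

$P_k$ are the observer's Big Five scores on the raw 1–7 questionnaire scale,
entered uncentred. We keep the raw scale because the simulation convention
downstream fixes non-swept traits *at the score 3*, which is only meaningful
on the raw scale. Each cell is fitted independently — the estimands are
per-region, per-impression, per-condition coefficients, and the model shares
no parameters across regions — which matches how results are reported
(separate significance tables per condition with one row per credible
region × predictor effect).

### Priors

* Fixed effects (both intercepts, all ten trait coefficients):
  Normal(0, 10). On the logit scale this is diffuse: a one-point change in a
  trait score shifting the odds by $e^{10}$ is far outside it.
* Random-effect scales $\sigma$: Gamma(shape 10, rate 10), mean 1, sd
  $\approx$ 0.32. A gamma prior on the *signed* effects themselves would be
  incoherent (they must be allowed to be negative), so the package attaches
  it to the four scales, the only coherent placement; the effects are
  Normal(0, $\sigma$).
* Beta precision $\phi$: Exponential(rate 0.1), mean 10, weakly informative.
  $\phi$ controls how concentrated positive dwell weights are around $\mu$
  ($a + b = \phi$). The choice is exposed in `zib_prior()` and overridable.

### Sampling

`fit_zib()` runs 4 chains of 2000 iterations with 1000 warm-up and no
thinning by default, retaining 4000 draws. Two backends are provided:

* **`"jags"`** (default): the model expressed in JAGS. Exact
  reparameterisations (unit Jacobian, the posterior is unchanged) are applied
  for mixing: predictors are mean-centred with the intercept prior rewritten
  by the corresponding change of variables, and both random-effect factors
  are hierarchically centred with the linear predictor split between them —
  the sampled subject node is $\beta' P_i + r^{subj}_i$ (the trait scores
  are subject-level predictors, so placing them in the subject prior mean
  gives the coefficients conjugate normal conditionals) and the sampled
  picture node is $\alpha + r^{pic}_j$, their sum being the row-level
  predictor. Raw-scale intercepts and random effects are recovered as
  derived quantities. This removes the slow couplings of the naive
  parameterisation (coefficients vs subject effects, intercept vs picture
  effects), which otherwise keep split-$\hat R$ above 1.1 at realistic cell
  sizes. The Bernoulli indicator $z = (G > 0)$ and the positive weights
  factorise the ZIB likelihood exactly into a Bernoulli regression on all
  rows plus a Beta regression on the positive rows, so no custom likelihood
  is needed inside JAGS; the `glm` module supplies block samplers for the
  conjugate sub-graphs.
* **`"mh"`**: a self-contained blocked adaptive random-walk Metropolis
  sampler written in R that targets `zib_log_posterior()` directly — the
  same density that is unit-tested against a brute-force oracle. Fixed
  effects move in two 6-dimensional blocks with covariance adapted during
  warm-up (frozen afterwards, so the chain is Markovian when sampling);
  $\phi$ and the scales move on the log scale with the Jacobian included;
  random effects are updated by element-wise parallel scalar proposals,
  valid because their full conditionals factorise over participants and over
  images. It mixes more slowly per iteration and serves mainly as an
  independent cross-check of the JAGS backend, which the test suite
  exercises.

Numerical guards: the logistic link uses `plogis` (saturates without
overflow), the Beta log density is evaluated through log-gamma functions,
and weights are nudged into $[10^{-9}, 1-10^{-9}]$ only at the Beta branch
boundary.

### Convergence and credibility

Convergence is declared per fit when it has at least 3 chains and
*split*-$\hat R$ (each chain halved before the between/within variance
ratio, which also catches within-chain trends) is below 1.1 for every
parameter, including every random effect. Non-converged fits are excluded
from significance tables with a loud warning rather than an error, mirroring
reporting practice.

Credibility uses the 95% highest-density interval, computed by the
Chen–Shao sliding-window search over sorted draws: the shortest contiguous
window containing $\lceil 0.95\,n \rceil$ draws, ties broken at the lowest
start. This construction is deterministic given the draws and is verified
exactly against an exhaustive window search in the tests. A trait effect is
reported when its HDI excludes 0.

## Preprocessing gaze streams

`build_weight_table()` turns raw gaze samples into dwell weights in four
steps, each pinned down where the procedure is conventionally
under-specified:

1. **Screen to image** — the 412 × 558 stimulus is centred in the
   1920 × 1080 screen, so the offset (754, 261) is subtracted; samples off
   the stimulus are *discarded*, not clipped (clipping would pile spurious
   mass onto edge regions). Coordinates are 0-based, origin top-left.
2. **Density map** — one unit per sample at its pixel, convolved with an
   isotropic Gaussian (SD 10 px, truncated at 4 SD with the kernel
   renormalised — a standard numerically safe choice), then normalised to
   total mass 1.
3. **Region weights** — density summed over each region's mask pixels and
   divided by the region's pixel area, giving mean per-pixel weight.
4. **Unified scale** — the six area-corrected weights are divided by their
   sum, so each trial's weights are comparable across trials and lie inside
   the Beta support; values below $10^{-6}$ of the trial maximum are zeroed
   first (smoothing otherwise leaks a trace of mass everywhere and the
   Bernoulli part would never see a zero), and a weight reaching 1 is
   clamped to $1 - 10^{-6}$.

The per-trial normalisation in step 4 is a documented design choice, not an
inference: a per-participant or global normaliser would also produce weights
in $[0,1)$, but only the per-trial version guarantees every trial the same
scale regardless of how much of its gaze fell on the face. Whether
background mass should enter the normaliser is equally open; it is excluded
here so that the six weights describe the *distribution of facial attention*
rather than face-versus-background attention.

## The synthetic experiment generator

`generate_experiment()` emulates the study design: 42 participants with Big
Five profiles, 50 trials per condition each (10 images fixed to each of the
5 impression items), 3 s of 120 Hz gaze per trial on a 412 × 558 stimulus
centred in a 1920 × 1080 screen, six facial regions, free and
aperture-restricted conditions. Two fidelity levels are generated:
*weights* (dwell weights drawn directly from a ground-truth ZIB model with
realised crossed random effects — the level used for parameter-recovery
studies) and *gaze* (each trial's weights converted into a sample stream so
the preprocessing chain can be tested end to end).

Choices the design leaves open, fixed once here:

* Trait scores are uniform on the 7-point grid (no population distribution
  is given); any discrete support can be substituted.
* Ground-truth baselines give each region a realistic dwell probability
  (0.45–0.85 at the scale midpoint) and dwell share (0.05–0.35); "moderate"
  effects plant one ±0.3 Bernoulli and one ±0.15 Beta coefficient per cell
  (per scale point, on the logit scale), i.e. effects spanning 1.8 / 0.9
  logits over the full 1–7 range; truth random-effect scales are 0.8. The
  restricted condition shifts dwell probabilities up by 0.5 logits,
  reflecting that an aperture forces at least a brief visit to most regions.
* Gaze samples are placed at region target points (the centroid, or the two
  component centroids for the bilateral eyes/eyebrows whose joint centroid
  falls off-region) with isotropic 10 px jitter, chosen so the SD-10 density
  filter recovers allocations cleanly; leftover budget goes to background
  pixels.
* The restricted condition collapses gaze and cursor into one trajectory
  that starts at the canvas centre and visits regions in order of distance
  from it — the simplest structure consistent with cursor-contingent
  viewing. The aperture presets are 40 px hard radius + 40 px Gaussian
  fall-off (the ~2° window) and 60/60 (the ~3° window, scaled linearly from
  the ~80 px total extent of the 2° geometry, since no pixel value is stated
  for 3°).

What the generator deliberately does **not** emulate: photorealistic faces,
saccade/fixation microstructure, blinks, calibration drift, or any
eye-tracker noise beyond isotropic jitter. Passing recovery tests on this
generator therefore demonstrates that the pipeline and model are correct
and well calibrated *under the model's own assumptions*; it cannot certify
behaviour on real gaze data whose noise violates them.

Because the pipeline divides region mass by pixel area, recovered weights
are proportional to allocation/area, not to raw allocation; recovery is
therefore assessed against the planted allocation expressed on the
pipeline's own area-normalised scale.

## Trait sweeps

`trait_sweep()` reproduces the model-based simulations: one trait sweeps the
integer grid 1–7 while the other four are fixed at 3 (the stated convention,
kept even though the scale midpoint is 4), random effects set to 0 — the
population mode under the symmetric effect prior. For every posterior draw
and grid point the Bernoulli probability $q$ (focus probability) and Beta
mean $\mu$ (dwell frequency) are evaluated and only then summarised
pointwise (mean and 95% HDI): the draw-wise order matters because the
logistic is nonlinear, and a plug-in of posterior means would be biased for
skewed posteriors — a property the tests check explicitly. $\mu$ is the
reported "frequency of focus" statistic, since the Beta part is the one
directly tied to degree of focus; the unconditional expectation $q\mu$ is
available via `include_qmu = TRUE`. `condition_difference()` subtracts free
from restricted sweeps draw by draw (positive = restricted dominant), and
intervals are always computed and exported even where a graph might omit
them for readability.

## Problem sizes used by the tests

The test suite and acceptance script run entirely on synthetic data at desk
scale, the package's own choice of study size for each property: single-cell
fits use 20 participants × 10 images (200 observations, the same order as
one cell of the real design); parameter recovery uses 20 independent seeded
datasets and null calibration 12; the end-to-end gaze-fidelity check uses a
few dozen trials. The default sampler configuration (4 × 2000/1000) is used
where the draw accounting and convergence behaviour of the stated settings
is itself under test, and shorter chains elsewhere.

## Known limitations

* Each cell is fitted independently; no partial pooling across regions or
  impressions, and no condition covariate — conditions are compared through
  simulation differences, not a joint model.
* The Bernoulli and Beta parts share no parameters, so a region that is
  almost always (or never) visited identifies one part weakly; an all-zero
  cell leaves the Beta part at its prior (the fit warns).
* HDI-excludes-zero is a per-coefficient decision rule with no multiplicity
  control across the 60 cells × 10 coefficients of a full run; the null
  calibration property (≈5% flags under a null truth) is exactly the
  per-test rate, not a family-wise one.
* The MH backend is a cross-check tool; at realistic sizes the JAGS backend
  is the one intended for inference.
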