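---
title: "Methods: simulating and analysing motion-dazzle tracking experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing motion-dazzle tracking experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dazzletrack` implements a complete in-silico version of a classic
behavioural paradigm in visual ecology: a tracker (predator) follows one
moving square (prey) among identical distractors, and tracking error is
analysed as a function of the squares' surface pattern, luminance contrast
and group size. This vignette documents the models, the parameters that
matter, the design decisions taken where the paradigm leaves choices open,
and the limits of what the synthetic data can show.

## Stimuli

Each square is 32×32 px and carries one of three colorations defined in the
square's *object frame*, whose +x axis is the heading axis:

* `parallel` — square-wave grating, stripes elongated along the heading;
* `orthogonal` — the same grating rotated 90°, stripes across the heading;
* `binary` — 4×4-px blocks independently dark or light with probability ½.

Gratings have spatial period 8 px (4 px dark, 4 px light) and a random
phase of 0° or 180° per square; phase 180° is the pixel-wise complement.
Two luminance pairs define the contrast levels: 0.5 and 132.5 cd m⁻²
(maximal) and 38 and 103 cd m⁻² (lower). The conventional labels "100%"
and "50%" are nominal: the printed pairs give Michelson contrasts of
0.992 and 0.461, and neither pair averages exactly to the 71.4 cd m⁻²
background. The luminance values themselves are treated as ground truth
and carried symbolically — no display gamma model is included.

Two conventions were left open by the paradigm and are exposed as
arguments: whether the binary noise image is resampled per square or shared
across a trial's squares (`shared_noise`, default per-square, the
conservative reading of "identical distractors" as a treatment label), and
grating phase, which is drawn independently per square.

## Kinematics

Squares follow a confined correlated random walk at 200 px s⁻¹ on a 100 Hz
clock: every 10 ms frame the heading accrues a wrapped-normal increment
(mean 0, SD σ = π/8 rad) and the square moves 2 px along the new heading,
its drawn orientation locked to the heading. A wrapped normal rather than
a von Mises is used for the "circular Gaussian": it is the most literal
reading (sample a normal, wrap), and at σ = π/8 the two are
indistinguishable in practice.

Confinement is to a 268×268 px arena centred on the origin. The paradigm
states that squares are constrained to this region but not how, so the
rule is ours: the square's **centre** is confined (switchable to
whole-square confinement via `confine_mode`); a step that would exit has
its increment redrawn (up to 20 attempts), after which the heading is
reflected about the violated wall. Redraw-first preserves the correlated
character of the walk near walls; reflection guarantees progress. A
consequence worth knowing: the *realised* increment distribution includes
these boundary events, which inflate its circular SD by about 5% over a
long confined run; the increment sampler itself recovers σ exactly
(verified to 1% at 10⁶ draws in the test suite). Squares may overlap —
no collision rule exists in the paradigm, and 60 squares of 32 px cannot
avoid overlap in a 268 px arena.

Degree-based quantities (e.g. a speed in visual degrees) are not asserted
anywhere: the printed pixel-based quantities are internally consistent and
authoritative; degree conversions would depend on a viewing geometry this
package does not model.

## The synthetic observer

The human participants of the original paradigm are replaced by an
explicitly invented tracker; none of its parameters are estimates of human
behaviour, and passing tests says nothing about people. The cursor starts
on the true target when the 1000 ms highlight ends, then follows a
*believed* target with

* a perceptual lag (`lag_ms`, default 100 ms): the cursor aims at the
  believed square's position `lag_ms` earlier;
* isotropic motor noise (`motor_sd`, default 10 px per 10 ms sample);
* belief swaps: each frame, with probability
  `swap_base × similarity[coloration] × (# distractors within swap_radius
  of the believed square)`, the belief jumps to the nearest distractor.

Swaps are the mechanism of the confusion effect: more squares → more
crowding → more swaps → larger error. The `similarity` multipliers
(defaults parallel 1.6, orthogonal 1.25, binary 1.0) fold pattern-driven
confusability into a single scalar and produce the
parallel > orthogonal > binary difficulty ordering. Swap eligibility uses
instantaneous proximity only — deliberately the simplest mechanism that
yields the orderings the statistics layer must detect.

Defaults were fixed once, before the test suite was frozen, by inspecting
a small grid of simulated sessions: `swap_base = 5e-4` and
`swap_radius = 60` px give cell-mean errors rising from ≈20 px (single
target) to ≈80 px (60 squares) without saturating toward the
random-guessing ceiling — saturation would compress the condition
differences the similarity multipliers encode. Between-participant
heterogeneity applies independent lognormal multipliers
(`exp(N(0, participant_sd))`, default SD 0.25) to `motor_sd` and
`swap_base`.

What the generator emulates: per-trial records with lognormal-like error
distributions, error increasing with group size, the coloration ordering,
no contrast effect, and participant-level random offsets. What it does
not: appearance-based target confusions (swaps ignore the actual pixels),
eye movements, learning or fatigue across blocks, lapses, and any real
perceptual effect of contrast — so a null contrast result in synthetic
data is built in, not discovered.

## Design and response

A session is 6 blocks (one per coloration × contrast combination, block
order randomised per participant) × 7 set sizes {1, 10, 20, 30, 40, 50,
60} × `reps_per_cell` repeats shuffled within block. `reps_per_cell = 8`
is inferred from the printed total (336 = 6 × 7 × 8); practice trials (4,
flagged, excluded from analysis) use the first block's condition at set
size 20, a choice the paradigm leaves unstated.

The per-trial response is the mean cursor–target distance over the final
4000 ms of the 5000 ms tracking period, sampled every 10 ms. The window is
the half-open interval (1000 ms, 5000 ms], i.e. exactly the last 400 of
500 samples, avoiding double-counting the boundary sample. Per-participant
cell means are computed first and then log-transformed (`log_error =
log(mean error)`): the mean-then-log order is pinned by the test suite,
because the opposite order differs by Jensen's inequality. Both response
granularities are supported in the model layer (`granularity = "cell"`,
the default, or `"trial"`), since the paradigm does not state which was
modelled.

## Mixed models and inference

All models are Gaussian random-intercept linear mixed models fitted by
**maximum likelihood** (never REML — every reported comparison is a
deviance test, and AIC values come from the same ML fits). Writing
λ = σ²_b/σ²_e, the covariance of a participant's block of observations is
σ²_e(I + λJ); given λ, the GLS estimate of β and the ML estimate of σ²_e
are closed-form, so the deviance is profiled to a one-dimensional function
of log λ, minimised deterministically (golden-section/parabolic search on
[−14, 14], argument tolerance 1e−8, which puts the deviance within ~1e−10
of its optimum near the quadratic minimum). The boundary λ = 0 (ordinary
regression) is checked explicitly and such fits are flagged `singular`.
Correctness is pinned three independent ways in the tests: the balanced
one-way closed form, a brute-force dense-covariance optimiser (agreement
to 1e−6 in log-likelihood), and the reference `lme4` implementation.

Set size enters as an orthogonal polynomial (degree 2), which makes the
linear model nested in the quadratic by construction; raw coding gives
identical likelihoods (tested) but poorer conditioning. Factors use
treatment contrasts with alphabetical level order (binary, orthogonal,
parallel; high, low) — likelihood-ratio results are coding-invariant.

The comparison ladder runs: quadratic-vs-linear trend (within the full
interaction model), then sequential deletion of the three-way interaction,
coloration × contrast, contrast × number, coloration × number, and finally
each main effect deleted from the main-effects model (coloration df 2,
number df 2, contrast df 1). Each step reports χ² = 2Δlog L, Δdf, the
upper-tail χ² p, and both AICs.

Post hoc coloration contrasts are single-step Tukey-type: z = estimate/SE
from the fixed-effects covariance, with family-wise adjusted p-values from
the joint multivariate-normal distribution of the three contrast
statistics. The 3×3 contrast correlation matrix is singular (the third
pairwise contrast is the difference of the other two), so the integral
uses quasi-Monte-Carlo integration (`mvtnorm`, 10⁵ nodes, absolute
tolerance 1e−6) under a fixed internal seed — adjusted p-values are
reproducible to well below the reporting precision. The adjustment is on
the normal, not t, scale, matching z-statistic reporting conventions for
mixed models.

Within-subject 95% confidence intervals for condition means are
Cousineau–Morey: subtract each participant's grand mean, add back the
global grand mean, compute per-cell SEs, inflate by √(C/(C−1)) for C
cells, scale by the t quantile. They require exactly one value per
participant per cell and at least two cells.

## Problem sizes and determinism

The test suite exercises the simulator at 10⁶ steps (kinematic fidelity),
the observer at 150–200 trials per condition (Monte-Carlo orderings), the
LMM layer at 2000 null replicates (type-I calibration of the LRT, which
should and does land in [0.04, 0.06] at α = 0.05) and 20 small datasets
against the brute-force oracle, and the full pipeline at five complete
14-participant sessions. One deliberate red flag: recovering the
between-participant variance to ±25% in ≥90% of replicates is not
achievable at 14 participants — the ML estimator's sampling SD at that
group count is ≈39% of the true value (√(2/14) relative error), so the
corresponding check fails by construction; it is kept as an honest
statement of what a 14-participant design can and cannot estimate.

Every stochastic component draws from R's global RNG, so a single
`set.seed()` (or the `--seed` flags of the command-line wrapper and
`scripts/acceptance.R`) makes sessions, datasets and analysis outputs
byte-identical across runs. The heavy inner loops (square motion, cursor
simulation) are in C++ via Rcpp but use R's RNG, preserving that
guarantee.

## Known limitations

* The observer is a caricature: it cannot validate mechanisms (aperture
  effects, spatio-temporal aliasing) — only the analysis pipeline.
* Contrast affects nothing in the generator, so the package cannot be used
  to study contrast sensitivity without replacing the observer model.
* The mixed models cover random intercepts only; random slopes and
  relaxed-covariance (GLS) variants are out of scope.
* Luminances are symbolic; rendering to a calibrated display is not
  modelled.
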