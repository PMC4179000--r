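---
title: "Methods: band powers, kernel Fisher projections and the imbalanced quasiconformal-kernel SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band powers, kernel Fisher projections and the imbalanced quasiconformal-kernel SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eeger` implements a three-layer scheme for classifying the emotional
valence (pleasant vs unpleasant) and arousal (excited vs calm) of
single-trial multi-channel EEG epochs, together with the evaluation
protocol appropriate for its heavily imbalanced label distributions and a
synthetic cohort generator that makes the whole stack testable without
recording hardware. This vignette is the package's own account of the
model, its tunable parameters, the numerical choices made, and what the
synthetic experiments do and do not establish.

## Layer 1 — spectral band powers

Each channel of an epoch is band-pass filtered into five standard bands —
theta (4–8 Hz), alpha (8–13 Hz), low beta (13–20 Hz), high beta
(20–30 Hz) and gamma (30–45 Hz) — with a fifth-order Butterworth design,
and the power of a band is the mean of the squared filtered samples. The
per-channel five-vectors are concatenated in channel order, so an epoch
from an `N_c`-channel montage becomes a spectral-power (SP) vector of
length `5 N_c` (310 values for the 62-channel montage the reference
recordings used).

Numerical choices:

* The filter is realized as cascaded second-order sections derived from
  the analog prototype poles (band transform and bilinear step via the
  `signal` package's zero-pole-gain tools). A tenth-order band-pass
  polynomial in direct form is severely ill-conditioned for a 4–8 Hz band
  at 500 Hz; the cascade is not. The sections are applied with
  `stats::filter`, so filtering stays at C speed.
* Filtering is causal (forward-only) by default. Band power is a mean of
  squares and therefore phase-insensitive, so zero-phase filtering —
  available via `zero_phase = TRUE` — changes little beyond the shape of
  the onset transient.
* No transient is trimmed before averaging and no log transform or
  normalization is applied to the powers. The narrow low-frequency bands
  ring for roughly two seconds at 500 Hz, so tests that compare
  steady-state amplitudes against the designed magnitude response measure
  after a settle window of a few seconds; power-level comparisons
  tolerate the onset energy explicitly.

## Layer 2 — kernel Fisher discriminant projections

Layer 2 projects SP vectors onto a small number of discriminant
directions with two-class kernel Fisher discriminant analysis (KFDA)
under the Gaussian kernel
`K(z, z') = exp(-||z - z'||^2 / (2 sigma^2))`. The mapped data are
centered in feature space (double-centering of the Gram matrix), and a
direction `v = sum_i a_i phi(z_i)` is sought that maximizes the ratio of
between-class scatter to the total scatter of the centered data. In
coefficient space this becomes the generalized symmetric eigenproblem

```
B a = lambda (W + mu I) a,
B = (1/L) sum_p (1/n_p) (Kc 1_p)(Kc 1_p)^t,   W = (1/L) Kc^2,
```

solved by symmetric whitening of the regularized denominator. Points are
projected through centered test kernel columns; the `d`-dimensional
projection of an SP vector is its discriminant feature vector.

Three design points deserve comment:

* **Total vs within-class scatter.** The denominator uses the total
  scatter of the centered mapped data. For two classes the between-class
  matrix has rank one, and because total scatter = within + between, the
  two Rayleigh quotients are monotone transforms of one another: the
  maximizing direction is identical and the eigenvalues simply land in
  `[0, 1]`.
* **Directions beyond the first.** With a rank-one between-class matrix
  only the leading eigenvalue is substantially positive. Later directions
  are returned ordered by the same regularized quotient; they span a
  near-degenerate eigenspace, are useful as auxiliary coordinates for the
  downstream classifier, and are *not* individually identifiable — only
  direction 1 is stable under permutations of the training rows, and the
  tests assert exactly that.
* **Regularization.** `W` is singular whenever `L` exceeds the effective
  rank of the centered Gram matrix, which is the typical regime here
  (at most 100 training epochs against 310 dimensions). The default ridge
  is `mu = 1e-6 * trace(W) / L`; each returned coefficient vector is
  rescaled so `a^t Kc a = 1` and signed so its largest-magnitude entry is
  positive.

The kernel width is searched over multiples of the median pairwise
training distance and `d` over small integers; both are selected by the
cross-validation protocol below.

## Layer 3 — imbalanced quasiconformal-kernel SVM

The label counts of emotional self-assessment are rarely balanced (the
most extreme reference profile has 146 high-arousal vs 54 low-arousal
epochs). A soft-margin SVM trained on such data skews its boundary toward
the minority class. Layer 3 counters this twice over.

**Cost-sensitive dual.** The SVM dual is solved with separate box
constraints `0 <= alpha_i <= C+` (positives) and `0 <= alpha_i <= C-`
(negatives). The total budget `C` is split by class frequency,

```
C+ = #N / (#P + #N) * C,     C- = #P / (#P + #N) * C,
```

so the smaller class carries the larger penalty and only `(sigma, C)`
remain to be searched. With `C+ = C-` the solver reduces exactly to the
conventional SVM (verified against a brute-force QP enumeration). The
solver itself is sequential minimal optimization with
maximal-violating-pair selection, deterministic initialization at
`alpha = 0`, a violation tolerance of `1e-8` and an iteration cap of
`1e5`; the bias is averaged over all free support vectors rather than
taken from any single one, for numerical stability.

**Quasiconformal retraining.** After the first fit, the within-margin
support vectors `T = {x_i in SV : -1 <= D(x_i) <= 1}` mark the margin
region. A positive scaling function

```
Q(x) = sum_{x_i in T} exp(-||phi(x) - phi(x_i)||^2 / tau_i^2),
||phi(x) - phi(x')||^2 = 2 - 2 K(x, x'),
```

is largest near the margin and decays away from it, and the kernel is
re-shaped as `K~(x, x') = Q(x) Q(x') K(x, x')` — a positive diagonal
scaling of the Gram matrix, hence still positive semidefinite. Retraining
on the same data with `K~` and the same `(C+, C-)` magnifies the spatial
resolution of the margin region. A separable first fit with no
within-margin support vectors needs no re-shaping; the step-1 model is
then returned with a warning.

**The scale `tau^2`.** Each `tau_i^2` is the mean squared feature-space
distance from `x_i` to its `N = 3` nearest neighbours. The neighbour pool
is the within-margin set itself (with `N` capped at `|T| - 1`; a
singleton `T` falls back to the full training set). The pool matters: if
neighbours are drawn from the full training set, `tau^2` tracks the
overall sampling density, and in dense or nearly collapsed feature spaces
(a one-dimensional discriminant projection of separable classes being the
extreme case) the bumps become so narrow that `Q` vanishes everywhere off
the margin and the re-shaped kernel erases the fit. Anchoring the scale
to the margin region keeps the bump widths commensurate with the
structure being magnified. This is also the reading consistent with the
conformal-transformation literature, which computes the scale from
neighbouring support vectors.

This mechanism still has a regime: when feature-space nearest-neighbour
distances are vanishingly small relative to the class overlap (very dense
low-dimensional clouds), the transformation degrades rather than helps —
a known limitation, documented rather than patched around.

## Evaluation protocol

All error rates are the **balanced loss** `BL = 1 - (TPR + TNR) / 2`,
which a constant classifier cannot push below 0.5 regardless of
imbalance. The protocol is 2-fold cross-validation repeated over 10
independent runs (run `r` reshuffles with seed `base + r`); 2 folds
rather than 5 or 10 keep the minority test folds from becoming tiny.
Folds are stratified by label — the reference profiles reach a 2.70:1
imbalance, where unstratified halves can starve a class. Any feature
learning (the KFDA fit included) happens inside the training fold. Grid
search minimizes the mean balanced loss over all folds and runs, with
ties broken toward smaller `d`, then smaller `C`, then smaller kernel
widths, so results do not depend on grid ordering. The selection reports
the best grid point's cross-validated loss, as the reference protocol
does; an honest nested evaluation can be layered on top by wrapping
`grid_search()` itself in an outer loop, but the default reproduces the
published protocol. A `k`-nearest-neighbour baseline (`k = 3`, Euclidean
distance, distance ties toward the lower index, vote ties negative) and
two consistency analyses — leave-one-out error on two trial-disjoint
halves, and the protocol run separately on the first and second half of
each trial's recording — complete the layer.

## The synthetic cohort generator

The generator emulates the *statistical* structure the pipeline assumes,
not the physiology of EEG. Each epoch is a sum of one sinusoid per band
(random in-band frequency per band, random phase per channel, base
amplitudes 4, 5, 3, 2, 1.5 microvolts from theta to gamma) over
1/f-shaped plus white noise at one tenth of the total oscillatory power
(−10 dB). Emotional classes differ by multiplicative band-amplitude
factors; the defaults scale high-arousal epochs by 1.5 in high beta and
gamma and 0.7 in alpha, and high-valence epochs by 1.5 in theta and 0.75
in low beta — band choices made for learnability, asserting no
neuroscientific claim. Cohorts follow the published ten-participant label
profiles exactly: 200 epochs in 100 trials, two epochs per trial sharing
the trial's labels, trials assigned greedily to the four
valence-arousal quadrants so both label marginals are met exactly, then
shuffled deterministically under the cohort seed.

Because the classes are stationary sinusoid mixtures, the generator does
not reproduce nonstationarity, artifacts, volume-conduction correlations
between channels, or participant drift. A pipeline that passes on this
cohort is shown to recover multiplicative band-power structure under
pink noise and exact label imbalance — no more.

## Problem sizes and determinism

The test suite and the acceptance script scale the experiments to run
comfortably on one CPU: behavioral cluster fixtures use 200 points in 5
dimensions (five being a typical discriminant projection count, and the
regime in which nearest-neighbour feature scales are informative);
full-pipeline checks use 60-epoch, 8-channel cohorts with a
3 × 3 parameter grid and 2-run 2-fold cross-validation; null-cohort
calibration uses 10 seeds. Every random draw flows from named seeds
through one generator interface, so identical inputs and seeds give
byte-identical reports.
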