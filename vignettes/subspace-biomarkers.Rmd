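---
title: "Auxiliary-data subspace learning for MCI conversion biomarkers"
author: "mvslearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auxiliary-data subspace learning for MCI conversion biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvslearn)
```

## The method and its assumptions

`mvslearn` extracts low-dimensional biomarkers for discriminating
progressive from stable mild cognitive impairment (pMCI vs sMCI) out of
two aligned morphological feature views per subject — regional cortical
thickness and regional cortical volume. The key idea is *auxiliary
learning*: the projection from feature space into a class-label subspace
is learned not on the MCI subjects themselves but on Alzheimer's (AD) and
normal-control (NC) subjects, whose anatomical contrast is a magnified
version of the pMCI/sMCI contrast. This rests on three assumptions:

1. **Shared discriminative directions.** The features that separate AD
   from NC also separate pMCI from sMCI (pMCI being AD-like, sMCI being
   NC-like). If conversion were driven by anatomy unrelated to the AD/NC
   axis, auxiliary learning would project it away.
2. **View agreement.** Thickness and volume carry the same label
   information from different angles, so their projections are pushed
   toward each other (the cross-view consistency term).
3. **Local structure is informative.** Subjects close in feature space
   should stay close in the subspace; a kNN heat-kernel graph Laplacian
   per view enforces this.

The joint objective combines label regression (weight `lambda`),
cross-view consistency (`1 - lambda`), per-view graph smoothness
(`alpha`), and a ridge penalty (`beta`). Each projection block has an
exact closed-form minimizer given the other — a ridge-type symmetric
positive-definite linear system — so fitting alternates the two exact
updates from zero initialization. Exact block minimization makes the
objective trace provably nonincreasing; the solver treats any numerical
increase beyond `1e-9` relative as a contract violation and stops with an
error rather than silently continuing.

Target subjects are mapped through the learned projections with the
*training-set* transform, and the two projected views are fused as
`eta * |Fea_CT|^2 + (1 - eta) * |Fea_CV|^2` elementwise. The written form
of this fusion rule can be read either as a product of distinct factors
or as elementwise squares of the absolute values; the squares reading is
the only one consistent with both the formula's shape and the
absolute-value definition, and is what the package implements. The
self-weighting (each coordinate multiplied by its own magnitude) amplifies
confident subspace coordinates; no further normalization is applied.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `lambda` | label-regression weight in (0, 1] | 0.1 | selected operating point of the method; `1` turns the cross-view term off (useful for the ridge-limit test) |
| `alpha`  | graph-smoothness weight ≥ 0 | 0.1 | selected operating point |
| `beta`   | ridge weight > 0 | 10 | selected operating point; also guarantees the update systems are positive definite |
| `kCT`, `kCV` | kNN neighbour counts per view | 11, 3 | selected operating point |
| `eta`    | thickness weight in the fusion, [0, 1] | 0.03 | selected operating point |
| `sigmaCT`, `sigmaCV` | heat-kernel bandwidths | median heuristic | no principled fixed value exists across feature scales; the median of retained kNN distances adapts per view, and a fixed override is exposed |
| `standardize` | `"scale"`, `"zscore"`, `"none"` | `"scale"` | see below |

Grid search (`gridSearch()`) covers `lambda` 0.1–0.9, `alpha`
10^-3^–10^1^, `beta` 10^-1^–10^1^, `k` in {3, 5, ..., 15} per view and
`eta` in {q·10^-2^, q·10^-1^ : q = 1..9} — 119 070 combinations. Because
ranking is by test accuracy, the top row is a selection-on-test quantity;
the full ranked table is returned so that optimism is visible, and a
reduced-repeats screening mode keeps the full grid tractable.

## Why scale-only standardization

Thickness (mm) and volume (mm³) live on scales differing by orders of
magnitude, so features are divided by their training-set standard
deviation before fitting. They are deliberately *not* centered by
default. The label regression has no intercept; with column-centered
features and a binary one-hot `Y`, `X Y[,2] = -X Y[,1]` exactly, so the
two projection columns are exact negatives of each other and the squared
fusion collapses the two biomarker columns into one sign-free magnitude —
all class information is destroyed (we verified this analytically and
empirically: AUC drops to ~0.5 on strongly separated cohorts). Raw
morphological features are positive with large means, which gives the
regression an implicit intercept direction; scale-only standardization
preserves that structure while equalizing units. `"zscore"` is retained
as an option for diagnostics, `"none"` fits raw features.

## What the synthetic generator emulates

`generateCohort()` draws four groups (AD, NC, pMCI, sMCI) observed through
two views. Per subject, a shared latent draw and a view-private draw are
combined with weights `sqrt(rho)` and `sqrt(1 - rho)` — so within-class
variance is exactly 1 before measurement noise and `rho` is the fraction
of signal variance shared between views — plus independent Gaussian noise
(`noiseSd`). Class means differ only on the first `nInformative`
coordinates: AD at `+delta/2`, NC at `-delta/2`, and the MCI groups
interpolated with `mix` (default 0.25), encoding "pMCI is AD-like, sMCI is
NC-like" without asserting a quantitative proximity, which is not known.
Each region also carries a fixed positive baseline (thickness-like
2–3.5, volume-like 8–20) so the views have the positive means and ~5×
scale difference of real morphological data — without which the implicit
intercept discussed above would not exist in simulation either.

Defaults were fixed once, before any evaluation: the four group sizes of
the reference cohort (142/165/126/95), `d = 78` cortical regions,
`noiseSd = 1`, `rho = 0.5` (views share half their signal variance —
thickness and volume are biologically coupled but not redundant),
`delta = 1` (a moderate contrast: AD/NC clearly separable, pMCI/sMCI
hard, mirroring the real ordering of task difficulty), and
`nInformative = ceiling(d/4)` (atrophy concentrates in a minority of
regions).

What the generator does **not** emulate: realistic inter-regional
covariance (real atrophy is spatially correlated along networks),
site/scanner effects, age and sex confounds, measurement artefacts, and
class imbalance in feature variance. Passing tests therefore demonstrate
that the implementation is faithful to the model and that the method
recovers structure *of the kind it assumes*; they say nothing about
accuracy on real cohorts.

## Evaluation protocol

Two protocols are implemented because the method's main experiments and
its self-learning comparison differ in where projections are learned:

* **auxiliary** — projections and standardization learned once on the
  full AD/NC auxiliary set; cross-validation on the target only
  trains/tests the classifier. (Learning from a disjoint cohort cannot
  leak target test information.)
* **self** — inside every repeat and fold, projections are relearned from
  the target *training* folds only and applied to both train and test
  folds. An instrumentation test verifies the fold model is bit-identical
  when the held-out fold's features are corrupted.

Folds are stratified by default (an unstratified mode mirrors a plain
random division); per-repeat metrics are computed from *pooled*
out-of-fold predictions rather than per-fold averages, which avoids
undefined sensitivity/specificity on tiny folds. AUC uses the
rank/Mann–Whitney formulation with ties counted ½; classifier scores are
signed decision values for the SVMs and leaf class proportions for the
tree. Paired t-tests across repeats use the convention p = 1 for
identically zero differences and a flagged 0 for zero-variance nonzero
differences. Undefined metrics are returned as flagged `NA`, never
silently 0.

## Numerical choices and degenerate inputs

* Update systems are solved by Cholesky factorization; `beta > 0` makes
  them positive definite by construction. No explicit matrix inversion.
* Convergence: relative objective change `< tol` (default `1e-8`,
  `maxIter = 200`); the stopping rule is a package choice since no
  canonical rule exists for this alternating scheme.
* kNN ties are broken by lowest subject index (stable ordering); the
  affinity is symmetrized by elementwise maximum (union-kNN), the
  standard undirected reading that preserves all directed neighbour
  weights. Note the union graph's per-row degree is bounded below by k
  but *not* above by 2k — hub subjects can appear in many
  neighbourhoods.
* An all-coincident neighbourhood (median kNN distance 0) falls back to
  bandwidth 1, which yields the correct unit weights.
* Zero-variance features get scale 1 instead of a division by zero.
* A declared class with zero members in `encodeLabels()` warns instead of
  failing: the optimization stays well-posed and the case is useful in
  testing.
* Single-class training folds (possible unstratified) predict the
  majority class with a warning instead of crashing the repeat.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic
cohorts sized to exercise every code path at desk scale: oracle
comparisons on dozens of random instances with `d ≤ 20`, `n ≤ 40`;
protocol-level checks on cohorts of 80–200 target subjects with 20 CV
repeats; the chance-level control averages 5 independent null cohorts per
classifier (the 20 repeats of a single cohort are correlated, so only
between-cohort replication yields a valid standard error for the mean
accuracy); the size sweep uses `delta = 0.75`, where accuracy still grows
visibly with auxiliary-set size instead of saturating.

## Known limitations

* Exactly two views; no kernelization; no alternative optimizers.
* Dense linear algebra throughout — fine for cohorts of a few hundred
  subjects, not for thousands.
* The label subspace has dimension `c` = number of auxiliary classes
  (2 in practice), so downstream classifiers see 2-D inputs; that is the
  method's design, not a tunable bottleneck.
* Whether real experiments learned projections on all auxiliary subjects
  at once or per fold is ambiguous in general; both protocols are
  provided rather than guessing one intent.
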