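---
title: "Landmark-based connectivity gradients: model, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based connectivity gradients: model, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcga)
```

## The model

A connectivity gradient assigns every cortical vertex a coordinate along a
principal axis of variation in its functional connectivity profile. The
classical construction correlates every vertex with every other vertex
(`n x n`), converts connectivity profiles to pairwise affinities, and
reduces the affinity matrix to a few components. At full surface
resolution the dense matrix is the bottleneck: ~60,000 vertices mean
3.5 billion entries.

The landmark approximation replaces the second axis of that matrix with a
small set of `k` reference signals — individual vertices (sampled at
random or spread by farthest-point sampling) or parcel-average time
series. The stages, in order:

1. **Connectivity.** `CM_nk[i, j]` is the Pearson correlation between
   vertex `i`'s time series and landmark `j`'s; `CM_kk` is the same among
   landmarks.
2. **Thresholding.** Per row, the `m = ceiling(0.10 * k)` largest strictly
   positive entries are kept; everything else, including all negative
   correlations, becomes 0. `ceiling` guarantees at least one survivor for
   any `k`; restricting to positives reflects that the profile similarity
   of interest is carried by each location's strongest connections.
3. **Affinity.** `W[i, j]` is the cosine similarity between the
   thresholded profile of vertex `i` (a row of `CM_nk`) and that of
   landmark `j` (a row of `CM_kk`). Both profiles live on the shared
   landmark axis, so the comparison is well defined; because thresholded
   profiles are non-negative, `W` lands in `[0, 1]` in practice.
4. **Reduction.** Column-mean-centered PCA of `W`, no variance scaling.
   The scores of the top components are the gradients; the explained
   variance ratio uses the full spectrum as denominator.

Only `n * k` affinity entries exist, a `k / n` fraction of the dense
pipeline's storage (`approximation_cost()` reports the exact figures).
The reference pipeline `full_gradients()` is *defined* as the same
computation with every vertex its own landmark, which makes
"approximation error" exact and testable: at `k = n` the two code paths
produce bit-identical results.

When a precomputed dense group connectome is available instead of time
series, `fcga_from_dense_fc()` obtains `CM_nk` and `CM_kk` by averaging
the precomputed connectivity over each landmark's member vertices (or
selecting columns for vertex landmarks) and then applies stages 2–4
unchanged; thresholding happens after the averaging.

## Conventions that make results reproducible

* **Indices are 1-based** everywhere, matching R; external 0-based
  conventions are converted at the I/O boundary.
* **Landmark order** is ascending vertex index / parcel id, so affinity
  columns — and therefore PCA results — do not depend on selection order.
* **PCA signs** are fixed deterministically: each component is flipped if
  needed so its largest-magnitude loading is positive. Any sign
  convention is arbitrary; having one makes repeated runs bit-identical.
* **Farthest-point sampling** implements "uniformly distributed"
  landmarks: a seeded random vertex anchors the walk, the first landmark
  is the vertex farthest from the anchor, and each further landmark
  maximises the minimum distance to the set so far (ties toward the
  smallest index). The anchor only seeds the walk — it is not
  automatically retained — so a geometrically central vertex never enters
  the set by accident of seeding. Index-stride alternatives depend on
  mesh ordering; distance-based sampling does not.
* **Zero-variance rows** (dead channels) raise by default;
  `zero_variance = "zero"` downgrades them to zero correlations with a
  warning. Rows left all-zero by thresholding get zero affinities, again
  with a warning, so degenerate inputs stay auditable rather than fatal.
* **Parcel averages** are unweighted vertex means; label 0 means
  unassigned and is excluded everywhere.

## Comparing gradient sets

PCA solutions are arbitrary up to component order and sign — and, when
eigenvalues are close, up to rotation inside the near-degenerate
subspace. The package therefore offers:

* `procrustes_align()` — closed-form orthogonal Procrustes (rotation /
  reflection only, no scaling or translation): the orthogonal `R`
  minimising `||source R - reference||_F` via the SVD of
  `t(source) %*% reference`. Aligned coefficient columns need not remain
  mutually orthogonal (the rotation acts on the component axis), so
  aligned sets are flagged in provenance and exempt from the
  orthogonality validity check.
* `spearman_similarity()` — per-gradient Spearman rank correlation of the
  spatial maps. The default reports `|rho|`, the only well-defined choice
  for unaligned sets; signed mode is meant for post-Procrustes use.
* `vertexwise_profile_similarity()` — per-vertex correlation of the
  gradient profile (the vertex's coordinates across components) between
  two sets.
* `planted_map_recovery()` — for synthetic data with known maps: each
  planted map is projected onto the span of the estimated gradients and
  correlated with its projection. Working in the span is what resolves
  the rotational indeterminacy; with near-equal explained variances the
  individual axes are not identified, but the subspace is.

## Reliability

`icc_absolute_agreement()` implements ICC(2,1) — two-way random effects,
absolute agreement, single measure — from the ANOVA mean squares:
`(MS_rows - MS_err) / (MS_rows + (r - 1) MS_err + (r / s)(MS_cols - MS_err))`.
The agreement form is pinned by the scientific question (do repeated
acquisitions produce the *same numbers*?); single-measure matches
comparing individual acquisitions. `vertexwise_icc()` applies it per
vertex on one gradient's coefficients over a balanced subjects-by-repeats
panel; no imputation is attempted for unbalanced panels.

`discriminability()` is the nonparametric multivariate complement: over
all ordered same-subject measurement pairs `(i, j)`, the fraction of
other-subject measurements farther from `i` than `j` is, ties counting
one half (unbiased under exchangeability). Distances are Euclidean on
flattened coefficient matrices; measurements should be aligned to a
common reference before panel construction, since the statistic is not
invariant to per-measurement rotations.

## The prediction benchmark

Two ways to build `P * g` parcel-level feature tables from a cohort:

* **gradients-to-parcellation** — vertex-level gradients per subject
  (any landmark set), Procrustes-aligned to a group reference, then
  parcel-averaged;
* **parcellation-to-gradients** — parcel-average the time series first,
  run the same pipeline on the `P x P` system (all parcels as
  landmarks), align likewise.

The alignment reference is built from the cohort-average connectivity
matrices — the role a group-average connectome plays in practice — so no
single subject's noise becomes everyone's alignment target. With
multiple sessions, per-session feature vectors are averaged after
alignment, mirroring pooled repeated runs.

`ridge_cv_predict()` fits ridge regression (glmnet, `alpha = 0`) under
nested 10-fold cross-validation: the inner 10-fold loop selects the
penalty minimising held-out MAE on the outer-training portion only;
features are z-scored inside each training portion (outer and inner
separately), so no test statistics leak into the fit. Held-out
predictions are aggregated across folds, and MAE and Pearson r are
computed once per repeat on the aggregated predictions. The default
penalty grid spans `1e-3 * lambda_max` to `lambda_max` (the largest
absolute feature/centered-target inner product per observation) in 30
log-spaced steps; ties in the inner selection resolve toward the larger
penalty. `permutation_baseline()` reruns the whole machinery on shuffled
targets and locates the observed performance with the add-one estimator
`p = (1 + #(null >= observed)) / (1 + n_perm)`, which cannot return 0.
`compare_constructions()` runs both feature constructions with the same
master seed — every repeat uses identical fold splits in both arms — and
reports paired per-repeat MAE differences, a win count, and a paired
one-sided Wilcoxon signed-rank test with Bonferroni adjustment over the
caller's comparison family. No deconfounding between targets is
performed.

## What the synthetic cohorts emulate — and what they do not

`make_toy_cortex()` builds a planar grid standing in for a cortical
surface: it preserves what the pipeline actually consumes — spatial
smoothness, coordinates for distance-based sampling, nested block
parcellations — while avoiding mesh geometry entirely.

The generative model is low-rank: `X = L diag(s) S + E`, with `L` the
`n x m` orthonormal planted maps (smoothed seeded noise), `s` strictly
decreasing component scales, `S` unit-variance component time courses,
and `E` i.i.d. sensor noise. Vertex connectivity is then rank-`m` plus
noise, and the planted maps are the ground-truth gradients. Subjects
receive individualized maps: a smooth perturbation field, unit-normalised
per component so that `subject_perturbation_sd` reads as the *relative*
deviation from the group map (0.2 is roughly an 11 degree rotation), is
added and the result re-orthonormalised by the symmetric (polar) factor —
the closest orthonormal matrix, which neither mixes columns the way
Gram–Schmidt does nor flips signs relative to the group. Sessions of one
subject share maps and differ only in time courses and noise. Behavioral
targets are linear readouts of the subject maps through a vertex-level
weight matrix (`make_behavior_weights()`): `parcel_mean` mode loads on
parcel-average map structure, `within_parcel_contrast` mode on structure
that parcel-averaging the *time series* destroys by construction.

Design choices behind the validation studies, made once:

* **Planted-map recovery** (n = 2000, m = 5, T = 500, noise 0.1, k = 200
  uniform landmarks) uses maps with equalised per-vertex norms, low
  smoothness, and near-equal scales (`10 * seq(1.05, 1)`): the
  threshold-cosine-PCA pipeline embeds *normalised* connectivity
  directions, so these are the conditions under which all planted
  components are representable — equal row norms mean every vertex
  carries a full-strength profile (as in amplitude-homogeneous BOLD
  data), and near-equal scales keep the latent directions isotropic.
  Recovery is scored with `planted_map_recovery()` against the
  conventional 25-gradient set.
* **The landmark-fraction sweep** uses n = 2400 so that the smallest
  fraction (0.5%) still yields 12 landmarks — a centered affinity matrix
  with 10 landmarks has rank at most 9 and cannot produce the 10
  components being compared. Components are Procrustes-aligned to the
  full-matrix reference before per-component Spearman; without alignment
  the per-component pairing is dominated by order and sign swaps among
  near-degenerate components.
* **The prediction benchmark cohort** (20 x 20 cortex, P = 20, 50
  subjects, 4 sessions, T = 500, perturbation 0.35, noise-free behavior
  loading on the first component's parcel means) realises the
  fine-vs-coarse contrast through estimation quality: the fine-grained
  arm uses 100 uniform vertex landmarks — a denser landmark set than the
  feature parcellation, as fine-grained gradient studies use in practice
  — while the coarse arm is locked to the `P x P` system, whose 20-point
  embedding (with only 2 surviving connections per row at the 10%
  threshold) is far noisier. Pure within-parcel-contrast behavior, by
  contrast, leaves *both* arms near chance at desk scale: the only route
  by which parcel-averaged fine gradients see within-parcel structure is
  the curvature of the embedding, a second-order effect. The contrast
  mode remains available for experiments, but the canonical benchmark
  uses the mechanism that is actually decisive at these sizes.

What passing these studies does *not* show about real data: the toy
cortex has no mesh topology, no geodesic distances, no hemispheric
structure; noise is white (no autocorrelation, motion, or physiological
artifacts); subject differences are a single smooth rotation of the map
basis; and behavior is exactly linear in map structure. The studies
validate the *machinery* — that the approximation converges to the full
pipeline, that reliability statistics read what was planted, that the
prediction harness is leak-free and directionally sensitive — not
empirical claims about any particular dataset.

## Numerical notes and limitations

* Problem sizes in the validation suite (n up to 2400, T = 500, 50
  subjects) were chosen so the planted effects are comfortably resolved
  at desk scale; `full_gradients()` carries an explicit memory guard
  (default 20,000 vertices) and errors with a pointer to `fcga()` beyond
  it.
* Correlations and cosines are clamped to `[-1, 1]` against rounding
  drift; rank is checked before PCA and reported in the error when a
  request exceeds it.
* Thresholding keeps ties by descending value with first-occurrence
  order, so results are deterministic for any input.
* The landmark-by-landmark block retains self-correlations; at very
  small `k` (around 10 at the default threshold) the kept entries are
  dominated by the diagonal and the coarse embedding degenerates — one
  reason fine landmark sets outperform very coarse parcellations.
* ICC confidence intervals, generalized (multi-set) Procrustes, and
  learners other than ridge are out of scope; gradient extraction is PCA
  only (no diffusion-map or Laplacian variants).
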