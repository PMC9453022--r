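---
title: "Degree-centrality mapping and classification: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-centrality mapping and classification: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodc)
```

# The problem

Obstructive sleep apnea (OSA) frequently co-occurs with mild cognitive
impairment (MCI), conventionally operationalized as a Montreal Cognitive
Assessment (MoCA) score below 26. A candidate imaging marker for separating
OSA patients with and without MCI is voxel-level **degree centrality (DC)**
computed from resting-state fMRI: for each gray-matter voxel, the strength
of its supra-threshold positive correlations with every other gray-matter
voxel. `neurodc` implements that marker and the full analysis around it —
atlas feature extraction, two-stage feature selection, and three-classifier
evaluation under leave-one-out cross-validation (LOOCV) with permutation
testing — together with a synthetic cohort generator that plants known
degree differences, so every stage can be validated against ground truth.

# The degree-centrality model

For in-mask voxels $i = 1, \dots, N$ with time series $x_i$, let
$r_{ij} = \mathrm{cor}(x_i, x_j)$. The weighted degree of voxel $i$ is

$$ D(i) \;=\; \sum_{j \neq i,\; r_{ij} > r_0} r_{ij}, $$

and the binary variant counts the same edges instead of summing them. The
threshold $r_0 > 0$ removes weak and all negative edges. Choices and
rationale:

* **`r0 = 0.25` by default.** The DC literature and the standard
  preprocessing toolchains use 0.25 as the conventional cutoff; the value
  is configurable and always recorded in output provenance.
* **Weighted degree is the default** because the defining sum adds the
  correlation values themselves; binary degree is offered because "degree"
  in graph terms often means edge count. Both variants are tested against
  a dense brute-force oracle.
* **Chunked computation.** The $N \times N$ correlation matrix is never
  materialized: rows are standardized once so a chunk of correlations is a
  single matrix product, and degrees accumulate chunk by chunk. The
  contract is equivalence with the dense computation to $10^{-10}$, for any
  chunk size — not a particular blocking scheme.
* **Zero-variance voxels are an error**, reported with their 3D
  coordinate, since a correlation against a constant series is undefined.

## The z transformation

"Transform the DC map to z values" admits two readings, and the package
implements both:

* `map_standardize` (default): standardize the finished degree map across
  in-mask voxels, so each subject contributes a zero-mean, unit-SD zDC map.
  This matches the common "zDC" feature definition and makes subjects
  comparable regardless of their overall connectivity level.
* `fisher_rz`: apply Fisher's $\tanh^{-1}$ to each correlation *before*
  summation (with $|r|$ clipped to $1 - 10^{-7}$). This improves normality
  of the summands rather than of the map; it must be computed from the
  original series, so `to_z_map(..., method = "fisher_rz")` asks for the
  recording and recomputes.

A degenerate map (zero variance across voxels) cannot be standardized and
errors out rather than returning NaNs.

## Smoothing

Smoothing scatters the z values into the 3D grid (zeros outside the mask),
convolves with a separable isotropic Gaussian of full width at half maximum
`fwhm_mm` (default 6 mm; $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per
axis, converted to voxel units), truncated at $4\sigma$, then re-masks.
This mirrors the behavior of the standard volumetric tools, which smooth
the whole volume and mask afterwards. Consequences worth knowing:

* a constant map is **not** exactly preserved near the mask boundary,
  because out-of-mask zeros bleed in — exactly as in the standard tools;
* the `renormalize = TRUE` variant divides by the smoothed mask indicator,
  making in-mask values weighted averages of in-mask neighbors only; that
  variant does preserve constants and is the right choice when boundary
  bias matters more than tool compatibility;
* `fwhm_mm = 0` is the exact identity, and the impulse response of the
  default variant equals a directly evaluated truncated discrete Gaussian
  (tested to $10^{-8}$).

# Feature extraction

Features are atlas region means of the smoothed zDC map: for region $k$,
the arithmetic mean over in-mask voxels labeled $k$, in a fixed region
order, with the class label MCI if and only if MoCA $< 26$ (a score of
exactly 26 counts as unimpaired). Region mean — rather than median or
maximum — is the standard parcellation reduction. Any labeled volume on
the same grid can serve as the atlas; tests use the package's toy Voronoi
parcellation so nothing needs downloading. Feature tables are written as
TSV with 10 significant digits, enough that a write–read–write cycle is
byte-identical.

# Feature selection

Two stages, mirroring a common neuroimaging-classifier recipe:

1. **Correlation pruning** (`correlation_prune`, threshold 0.75): while any
   retained pair has $|r|$ above the threshold, take the worst pair and
   drop the member with the larger mean absolute correlation against all
   other retained features, recomputing after each removal. This is the
   iterative (caret-style) rule; a single-pass variant sits behind
   `iterative = FALSE`. On exit no retained pair exceeds the threshold,
   and the operation is idempotent.
2. **L1-penalized selection** (`lasso_select`) over the 46-point grid
   $\alpha = 10^{-6}, 10^{-5.8}, \dots, 10^{3}$. For each $\alpha$,
   stratified $k$-fold cross-validation (default 10) of an L1-penalized
   logistic model, scored by the **mean squared error between the predicted
   MCI probability and the 0/1 label**. "L1 logistic scored by MSE" honors
   both halves of the usual description of this procedure — the model is a
   classifier, and probabilities make MSE well defined; a pure linear
   lasso on the 0/1 labels is available via `mode = "linear"`. Ties in CV
   MSE resolve toward the larger penalty (the sparser model). The final
   model is refit on all data at the chosen penalty and coefficients with
   magnitude above $10^{-8}$ are reported.

Features are z-standardized before penalization so the penalty is
scale-equitable; inside CV the standardization parameters are learned on
the training folds only. Penalty values are glmnet's $\lambda$ in the
objective $-\ell/n + \alpha\|\beta\|_1$. When a requested grid is short,
warm-up penalties are prepended so coordinate descent starts from the fully
shrunk model; solutions are read off only at the requested penalties. At
penalties near $10^{-6}$ on separable data the optimizer legitimately
cannot converge (coefficients diverge); path solutions at larger penalties
are used, and such penalties never win the CV anyway.

# Classification and evaluation

Three classifiers run under one protocol: linear-kernel SVM (linear because
per-feature weights are part of the report), random forest, and
L2-regularized logistic regression (penalty expressed as `C`, with
$\lambda = 1/(nC)$). For each left-out subject the remaining $n-1$ are
standardized, hyperparameters are chosen by an inner stratified 5-fold grid
search scored by accuracy (default grids: `C` in $\{0.01, 0.1, 1, 10,
100\}$ for SVM and LR; trees in $\{100, 500\}$ and depth in
$\{\infty, 3, 5\}$ for RF), and the held-out subject is scored — by signed
decision value (SVM) or MCI probability (RF, LR). Inner folds shrink
automatically when a class is too small to keep two training members per
class.

Reported metrics, MCI positive throughout: confusion counts, accuracy,
sensitivity, specificity, pooled-score AUC, and Cohen's kappa
$(p_o - p_e)/(1 - p_e)$ (defined as 0 when $p_e = 1$). The ROC is a single
curve over all held-out scores, and its AUC is computed by the rank-based
Mann–Whitney construction with half-credit ties — tested to $10^{-12}$
against pairwise enumeration and an independent ROC implementation.

**Permutation testing** uses the pooled-LOOCV AUC as its statistic and the
add-one rule $p = (1 + \#\{\mathrm{AUC}_{\pi} \ge \mathrm{AUC}\})/(B+1)$.
Three selection protocols are available: `none` (features fixed),
`per_permutation` (prune + penalized selection re-run on the full data for
the observed labels and for each shuffle — the exchangeable protocol used
in the calibration checks), and `nested` (selection additionally re-run
inside every LOOCV training split). Re-using a single selection computed
once on the observed labels inside the permutation scheme would not be
exchangeable; the package's leakage test demonstrates the related bias
directly: on label-independent data, selecting features once on all data
before LOOCV yields optimistically biased AUC relative to per-fold nested
selection.

A related subtlety: under the null, LOOCV hard-label accuracy sits
slightly *below* 0.5 at small $n$, because leaving one subject out tilts
the training majority toward the other class. The bias decays roughly as
$1/n$; calibration checks therefore run at the study scale ($n = 100$),
where the deviation is well within sampling noise.

# The synthetic cohort generator

Each subject's recording is built per voxel as
$x_v = w_v \cdot \ell_{R(v)} + \sigma \varepsilon_v$, where $\ell_R$ is a
region-shared latent N(0,1) series, $\varepsilon_v$ iid noise, and the
coupling $w_v$ equals `base_coupling` except in the designated effect
regions of group-1 (MCI) subjects, where it is raised by `effect_size`.
Expected within-region correlation is $w^2/(w^2 + \sigma^2)$ — verified by
simulation — so planted effects translate into known degree differences.
Series are mean-centered; latents can optionally be band-limited to
0.01–0.08 Hz at a 2 s sampling interval by FFT masking (off by default,
since degree depends only on the correlation structure). MoCA scores are
drawn uniform on [18, 25] for group 1 and [26, 30] for group 2 — only the
"< 26" rule matters downstream. Per-subject seeds derive from the master
seed by a fixed 32-bit multiplicative hash (`derive_seed`), so any subject
can be regenerated independently on any platform.

Study conditions used by the calibration checks, chosen once and fixed:
groups of 51 and 48 subjects, 240 time points, base coupling 1, noise SD 1
(within-region $r = 0.5$), an 8-region atlas with the effect planted in 4
regions (a modest subset of regions carrying signal, as in the motivating
analyses), and `effect_size = 0.12` — calibrated by a one-off simulation
sweep (0.05 → d ≈ 0.4, 0.08 → 0.7, 0.10 → 0.85, 0.12 → ≈1.0,
0.15 → 1.25) so the region-mean zDC separation is about 1 SD. Note the
map standardization makes planted effects partially *relative*: raising
degree in half the regions pushes the standardized means of the remaining
regions down, which adds discriminative signal beyond the effect regions
themselves.

What the generator does **not** emulate: hemodynamic response shapes, head
motion, physiological noise, spatial autocorrelation of real zDC maps,
scanner or site effects. Passing tests therefore demonstrate that the
pipeline recovers planted correlation-structure differences and is
calibrated under a true null — not that real patient data would classify
at any particular accuracy.

# Problem sizes and numerical choices

Desk-scale defaults keep everything runnable in minutes on one core: a
16×16×16 grid at 3 mm with a ~2,000-voxel spherical mask (the full
61×73×61, ~67k-voxel template scale remains a configuration option), DC
oracle checks at a few hundred voxels, calibration runs with 20 replicates
and 99 permutations, and null-accuracy checks at $n = 100$ over 50 seeds.
Other numeric conventions: correlations are clipped at $1 - 10^{-7}$
before $\tanh^{-1}$; kernel truncation at $4\sigma$ with per-axis kernel
normalization; nonzero-coefficient threshold $10^{-8}$ on standardized
coefficients; prune ties drop the earlier column; grid-search ties keep the
earlier grid point; empty selections fall back to the pruned (or full)
feature set so downstream stages always have input.

# Known limitations

* The pipeline's default protocol — selection on all data, then LOOCV —
  mirrors common published practice but is optimistically biased; the
  nested options exist precisely to quantify that. For honest error
  estimates use `selection_mode = "nested"`.
* Printed-summary t-tests inherit the rounding of the published mean/SD
  values; agreement with published p-values is expected only to ~0.005.
* Kappa values published alongside sensitivity/specificity pairs are not
  always jointly consistent with the implied confusion counts; the package
  reports the closed form from its own confusion matrix and does not force
  agreement with any external table.
* The toy Voronoi atlas is a stand-in: regions are contiguous-ish and
  nonempty but carry no anatomy. Any labeled NIfTI volume on the analysis
  grid can be substituted.
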