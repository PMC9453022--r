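# neurodc

Voxel-wise degree-centrality mapping and machine-learning classification
for resting-state fMRI, aimed at separating obstructive sleep apnea (OSA)
patients **with** mild cognitive impairment (MCI, MoCA < 26) from those
**without** (nMCI). The package implements the full analysis chain —
degree-centrality maps from masked 4D BOLD series, atlas region-mean zDC
features, two-stage feature selection, and SVM / random forest / logistic
regression evaluated by leave-one-out cross-validation (LOOCV) with
permutation testing — plus a synthetic cohort generator with planted,
known degree effects so every stage can be validated against ground truth.

## The model

For in-mask voxels $i = 1,\dots,N$ with Pearson correlations
$r_{ij}$ between voxel time series, weighted degree centrality is

$$ D(i) = \sum_{j \neq i,\; r_{ij} > r_0} r_{ij}, \qquad r_0 = 0.25
\text{ by default,} $$

with a binary (edge-count) variant. Maps are transformed to zDC
(per-subject standardization, or Fisher r-to-z applied pre-sum), smoothed
with a 6 mm FWHM Gaussian, and reduced to atlas region means. Features are
pruned at absolute correlation 0.75, then selected by L1-penalized
logistic regression over the grid $\alpha = 10^{-6}, 10^{-5.8}, \dots,
10^{3}$ with 10-fold CV scored by MSE on predicted probabilities.
Classifiers are compared on pooled-LOOCV AUC, accuracy, sensitivity,
specificity and Cohen's kappa; significance comes from label-permutation
tests with the add-one rule. The methods vignette
(`vignettes/degree-centrality-workflow.Rmd`) documents every choice,
default and limitation.

## Worked example

```r
library(neurodc)

geom  <- generate_toy_geometry(c(8, 8, 8), mask_rule = "all_in")
atlas <- generate_toy_atlas(geom, 8, seed = 11)
spec  <- cohort_spec(n_group1 = 51, n_group2 = 48, n_timepoints = 240,
                     effect_regions = 1:4, effect_size = 0.12, seed = 2001)
cohort <- simulate_cohort(geom, atlas, spec)

maps <- lapply(cohort$recordings, function(r) dc_pipeline(r$bold))
names(maps) <- cohort$participants$subject_id
ft <- build_feature_table(maps, atlas, cohort$participants)

sel <- select_features(ft, prune_threshold = 0.75, seed = 1)
sel
#> <selection_result> best alpha 1e-06 (CV MSE 0.0665); 6 nonzero of 6 features

held <- loocv_predict(model_spec("svm_linear", grid = list(C = 1), seed = 5),
                      ft)
compute_metrics(held$truth, held$pred, held$score)
#> <model_report> n=99 | AUC 0.958 acc 0.889 sens 0.882 spec 0.896 kappa 0.778
```

The report line reads: on a 51/48 synthetic cohort whose four effect
regions carry ~1 SD of region-mean zDC separation, the pooled held-out
SVM ranks MCI above nMCI subjects with probability 0.958 (AUC), classifies
88.9% of subjects correctly, detects 88.2% of MCI subjects (sensitivity)
and 89.6% of nMCI subjects (specificity), with chance-corrected agreement
0.778.

Demographics-style group comparisons work directly from printed summary
statistics:

```r
ttest_from_summary(list(n = 51, mean = 41.17, sd = 3.24),
                   list(n = 48, mean = 39.95, sd = 2.77))$p
#> [1] 0.04743712
chi2_yates(matrix(c(48, 3, 47, 1), 2, 2, byrow = TRUE))$p
#> [1] 0.6536084
```

An end-to-end run (simulation → DC → features → selection →
classification → demographics) with deterministic, hash-stable outputs:

```r
run_pipeline(default_run_config(seed = 17), out_dir = "run17")
```

A thin CLI over the same functions lives at `inst/cli/neurodc.R`
(subcommands `run`, `simulate`, `dc`, `features`, `select`, `classify`,
`stats`).

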