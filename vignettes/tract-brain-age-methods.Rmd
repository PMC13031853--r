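---
title: "Tract-specific white-matter brain age: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-specific white-matter brain age: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tractage` implements a normative-modelling analysis of white-matter
development from along-tract fractional anisotropy (FA) profiles: per-tract
Gaussian-process age models, bias-corrected brain-age gaps (BAGs), sparse
canonical correlation against behavior, group-level clinical models, and
spatial decoding of tract loading patterns against volumetric maps. This
vignette explains the models, their assumptions, the tunable parameters, and
the design decisions taken where the design was genuinely open.

## The data model

A subject's imaging feature set is the FA value at 100 equally spaced nodes
along each of 54 tracts (25 bilateral pairs plus 4 corpus callosum tracts;
see `tract_catalog()`). Tracts carry a *system* label — dorsal association,
ventral association, limbic, sensorimotor, thalamic, corticostriatal,
callosal — which organizes both the synthetic generator and the
interpretation of the sparse CCA modes.

## The synthetic cohort generator

`cohort_config()` / `simulate_cohort()` generate cohorts whose statistical
structure matches everything the downstream stages assume, so the whole
pipeline is testable without any restricted data. What is emulated:

* **Maturation.** Node-level FA follows a logistic growth curve
  `f0 + (f1 - f0) / (1 + exp(-k (age - t0)))` with per-tract parameters
  drawn once from the config seed (floors 0.25–0.4, gains 0.1–0.2, rates
  0.2–0.5 per year, midpoints 9–15 years, mild sinusoidal along-tract
  modulation). These ranges put node FA and its developmental change in the
  range typical for school-age-to-young-adult tractometry.
* **Planted deviations.** Each subject has a maturational deviation per
  tract system, in years (`deviation_sd`, default 2 — commensurate with the
  2-year scale of cross-validated brain-age errors in this age range). This
  deviation *is* the ground-truth BAG. Systems belonging to the same latent
  mode share a common factor (`system_cor`, default 0.5): association
  systems co-mature, and likewise the subcortical/limbic systems. This
  shared factor is what the mode's latent score captures — without it the
  "mode" would be a sum of independent blocks and no multivariate method
  could (or should) recover it as one pattern. Tract-level jitter
  (`tract_jitter_sd`, 0.3 years) sits on top.
* **Sites.** Per-site, per-feature additive shifts (SD 0.02 FA units) and
  multiplicative noise-scale factors (0.8–1.2), site 1 as reference — the
  structure ComBat models.
* **Noise.** I.i.d. node noise `noise_sd_fa = 0.03`, a realistic test-retest
  scale for node-wise FA; values are clipped to the valid FA range [0, 1]
  after noise and the clip count recorded.
* **Behavior.** 20 "cognitive" and 31 "psychopathology" measures. Block j of
  mode k loads on the standardized latent mode score with a scale chosen so
  the correlation between the latent score and the loading-weighted block
  composite equals `mode_coupling[k]` (defaults 0.3 and 0.2, the magnitude
  regime of developmental brain-behavior canonical correlations).
* **Diagnoses.** A liability negatively weighted (−0.3) on the standardized
  association-system deviation, thresholded to reproduce configured 0 / 1 /
  ≥2 diagnosis-class probabilities at baseline (0.752 / 0.156 / 0.092) and
  follow-up (0.793 / 0.142 / 0.065), with a correlated follow-up liability
  (r = 0.6) so that all four diagnostic-transition cells (healthy-persistent,
  remitted, new-onset, persistent) are realistically populated. The sign
  encodes the hypothesis under test downstream: delayed association-tract
  maturation carries psychiatric risk.
* **Puberty and hormones.** PDS item scores increase stochastically with age
  and deviation; salivary DHEA, testosterone and estradiol are log-normal in
  age and deviation and truncated to the standard QC plausibility ranges
  (5–1000, 5–500, 0–1500 pg/ml); saliva-collection covariates (caffeine,
  activity, collection time/duration, freeze time) are generated for the
  hormone mixed models.

What the generator does **not** emulate: spatial correlation of noise along
tracts, non-Gaussian FA artifacts, site-by-age interactions, attrition
correlated with symptoms, measurement invariance failures in behavior.
Passing tests therefore demonstrate internal statistical correctness and
recoverability under the stated model, not robustness to every real-data
pathology.

## Harmonization

`fit_combat()` is parametric empirical-Bayes ComBat with an explicit
fit/apply split: features are standardized against the covariate-adjusted
grand mean and pooled variance; per-site location and scale estimates are
shrunk under normal / inverse-gamma priors with method-of-moments
hyperparameters, iterated to a relative tolerance of 1e-4 (maximum 100
iterations) — the reference implementation's defaults. Biological covariates
(age, sex, and the diagnosis count class coded as two dummy columns) are
preserved. A single-site fit is the identity transform by construction,
since one batch leaves the scale-prior moments undefined. The pipeline
harmonizes each dataset on its own; pooling across datasets is the caller's
choice by concatenating before `fit_combat()`.

## Brain-age models

Each model unit is a bilateral pair (left nodes then right nodes, p = 200),
a callosal tract (p = 100), or the whole-brain concatenation (p = 5400).
`fit_gpr()` is an exact Gaussian process with an RBF kernel plus white
noise on internally standardized features; the kernel is a config-visible
choice, not a claim that it is the only reasonable one — it is the standard
choice in brain-age GPR work. Hyperparameters maximize the marginal
likelihood (analytic gradients, L-BFGS-B, seeded multiple restarts;
defaults: 2 restarts, 50 iterations). Predictions are posterior means
`k*' (K + sigma_n^2 I)^{-1} y`, checked against that closed form directly in
the tests. At the cohort sizes used here (hundreds of subjects) the exact
O(n^3) GP is comfortably tractable, so no inducing-point approximation is
used; the whole-brain model's cost is dominated by the one-off distance
computation.

Evaluation follows the two-stage design: a 20% age-stratified hold-out,
5-fold age-decile-stratified cross-validation on the remaining 80%
(`age_stratified_folds()`, seeded and recorded), with R and RMSE computed on
concatenated out-of-fold *uncorrected* predictions — bias-corrected
predictions are never used for performance reporting, which would flatter
the model. The permutation test refits the model on age-permuted data
(`permutation_test_R()`); its p-value uses the `(count + 1) / (n_perm + 1)`
convention, which cannot return 0. A fast linear engine is provided for
Monte-Carlo calibration studies of the permutation machinery, where
refitting a GP hundreds of thousands of times would serve no inferential
purpose.

The age-bias correction fits `BAG = alpha * age + beta` by OLS on the
training out-of-fold BAGs and subtracts the fitted line everywhere
(`apply_bias_correction()`). In-sample the corrected BAG is orthogonal to
age exactly; out of sample the regression-dilution-induced slope attenuates
by well over 80% in the package's simulations.

## Sparse canonical correlation

`scca_fit()` implements penalized matrix decomposition of the
cross-product `X'Y`: alternating soft-threshold updates with unit L2 norms
and L1 budgets `C * sqrt(dim)` — the budget is the `C` fraction of the
largest L1 norm an L2-unit vector can have. The thresholding step is solved
in closed form (the L1/L2 ratio is piecewise analytic in the threshold),
with bisection retained as a numerical fallback. Iteration runs to a 1e-6
change in `u` or 200 iterations; non-convergence warns. With both
constraints inactive (C = 1) every mode reproduces the corresponding SVD
singular pair to 1e-6, which the tests assert on random 30 × 51 problems.
Successive modes deflate `Z <- Z - d u v'`.

Open choices and how they were resolved:

* The sparsity grid runs 0.1–1.0 in steps of 0.1 on both sides (100
  combinations); 0 is excluded because it forces a zero vector. Selection
  averages the first-mode correlation over ten seeded two-thirds subsamples.
* Both raw sparse weights and *structure loadings* (variable–variate
  correlations) are reported; bootstrap CIs are computed on the structure
  loadings, whose sampling behavior is smoother than that of the sparse
  weights.
* Sign convention: each mode is oriented so the summed structure loadings of
  a designated block (the cognitive block in the pipeline) are non-negative.
  The second mode's sign is arbitrary with respect to that convention, so
  recovery checks against planted structure compare up to sign.
* Mode significance permutes the behavioral block's *rows* (subjects),
  preserving each column's marginal distribution, refits the whole model,
  and applies BH-FDR across modes. Bootstrap modes are aligned to the
  reference modes by maximal absolute correlation of canonical variate
  scores, with sign flips; ties are logged.
* Mode specificity compares paired bootstrap distributions of absolute
  loadings between modes; a variable is specific where the paired Cohen's d
  reaches 0.5.
* Covariate residualization (age, sex) is estimated on the full analysis
  sample, matching single-sample sCCA usage; it is not a prediction
  pipeline, so no train/test split applies.

## Group-level models

* `glm_bag_behavior()`: OLS of BAG on one behavioral score plus age and sex;
  the caller adjusts the full 30 × 51 family with `bh_fdr()`.
* `glm_group_effect()`: omnibus partial F (model comparison with and without
  the factor) for the diagnosis-count classes (0 / 1 / ≥2) or the four
  transition classes, then Tukey HSD on covariate-adjusted means via the
  studentized-range distribution, with the Tukey-Kramer form for the highly
  unbalanced groups; pass `age = NULL, sex = NULL` for raw group means. The
  partial F is computed from the RSS decomposition directly (numerically
  exact at zero effect).
* `gam_delta_r2()`: mgcv GAMs (penalized cubic spline in age, REML,
  basis dimension 10); the effect size is the change in adjusted R² (as a
  percentage) when the linear BAG term is added to the covariates-only
  model. Adjusted ΔR² can be slightly negative under the null; that is the
  statistic's behavior, not an error.
* `lmm_developmental()`: random-intercept models for pubertal stage and
  hormone predictors across the two visits, fit by REML with Satterthwaite
  degrees of freedom (lmerTest); singular fits are reported, not hidden.
  The pubertal-stage model uses the stage as the focal predictor — the
  printed model family is one formula with the hormone slot occupied by
  stage in the stage analysis.
* `pds_categorize()`: the sex-specific PDS staging rules, including the
  female menarche conditions, as a deterministic mapping.
* `effect_pattern_similarity()`: Spearman correlation of two tract-wise
  effect patterns; the p-value is computed by full permutation enumeration
  for up to 10 tracts (n! permutations) and by the t approximation above
  that.

## Spatial decoding

`tract_atlas()` holds per-tract probability volumes on one shared grid;
affines must match exactly — there is no silent resampling. Tract profiles
of a map are means over voxels at ≥50% tract probability (optionally inside
a grey-matter mask), z-scored across tracts. TRC and MRC follow their
defining formulas exactly: `TRC = (sqrt(CI) + sqrt(CII) + sqrt(CIV)) / 3`,
`MRC = TRC / MitoD`.

Significance uses variogram-matched surrogate nulls on tract centroid
geometry: a surrogate is a random permutation of the profile, smoothed by
distance-weighted kernels over a ladder of neighbourhood sizes (2, 3, 5, 8,
12 neighbours), linearly recombined with white noise so its variogram best
matches the empirical variogram over 25 quantile distance bins, then
rescaled to the observed mean and SD. Tract volumes have no spherical
parameterization, so a rotation-based null is not applicable; a single
variogram-matching engine serves both the functional (1000 surrogates) and
mitochondrial (10,000 surrogates) analyses, with the iteration counts kept
as defaults. Distance metric (Euclidean between probability-weighted
centroids) and bin count are exposed in the API. With fewer than 10 tracts
the generator falls back to plain permutation with a warning. Under
spatially uncorrelated inputs the surrogate null is indistinguishable from
plain permutation; under autocorrelation it is wider — both properties are
exercised in the tests.

## Pipeline

`run_pipeline()` chains simulate → harmonize → brain-age → sCCA → group
models → decoding from one `pipeline_config()`. Stages communicate only
through serialized TSV/JSON artifacts; every stochastic stage derives its
seed from the master seed; re-running with an identical config reuses
cached outputs keyed by a config hash, and the manifest records status,
wall time and MD5 checksums per stage. The default run disables the GP age
permutation test (`n_perm = 0`): a thousand GP refits per tract is a
cluster-scale computation, and the operation is available and tested on its
own. The decoding stage demonstrates the chain on synthetic Gaussian-blob
atlases; with real NIfTI atlases and maps, call `decode_maps()` directly.

## Problem sizes in the tests

The test suite chooses sizes so that each property is decisive yet the
whole suite stays desk-scale: deviation recovery runs the default cohort
(n = 600, 54 tracts × 100 nodes) at three noise levels with two
dorsal-association tract models; sCCA recovery uses 50 replicates of
n = 2000 cohorts with 2 nodes per tract (the BAG-stage input is what
matters there, not the node count); null calibrations use 100–500
replicates with reduced block dimensions, with binomial 99% bands as the
pass criterion; the end-to-end determinism check runs a 150-subject,
8-tract configuration twice. Monte-Carlo pass thresholds (recovery rate
≥ 0.8, direction rate ≥ 0.9, coverage band around 0.95) come from the
property definitions, not from observed outcomes.

## Known limitations

* The GP is exact; cohorts beyond a few thousand subjects would need
  inducing points or similar approximations.
* Parametric EB ComBat only — no GAM-ComBat (nonlinear age in the
  standardization step) and no longitudinal ComBat; visits are harmonized
  jointly with visit-invariant site effects.
* The PMD sign and mode-matching conventions make results deterministic but
  are conventions; loadings should be interpreted up to joint sign.
* The surrogate engine conditions on tract centroids; elongated tracts
  whose spatial extent matters beyond their centroid are represented only
  through the variogram.
* Diagnosis counts are modelled through the 0/1/≥2 classes the analyses
  use, not as full ordinal processes.
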