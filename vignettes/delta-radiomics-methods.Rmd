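---
title: "Delta-radiomics survival modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics survival modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltarad)
```

## The model

`deltarad` predicts progression-free survival (PFS) from the *change* in
quantitative tumor texture between a pre-treatment CT and a follow-up CT
acquired 6–16 weeks into therapy. The working hypothesis is standard in
delta radiomics: a responding tumor reorganizes internally (cellularity,
necrosis, vascularization) before its gross size changes, and that
reorganization is visible as a change in texture statistics of the ROI.

The statistical core is a Cox proportional-hazards model
\(h(t \mid x) = h_0(t)\exp(\beta^\top x)\) fit on a small set of selected
delta features, possibly joined with selected clinical covariates. All
risk outputs are linear predictors: higher = earlier expected
progression. The proportional-hazards assumption is inherited, not
tested, by the pipeline — a known limitation.

## Preprocessing

* **Resampling.** Volumes and masks are resampled to 1×1×1 mm (trilinear
  for intensities, nearest-neighbor for masks). The operation is
  idempotent at the target spacing and preserves the physical extent to
  within one voxel.
* **Normalization.** Z-scoring uses the *population* (divide-by-n) SD,
  over the whole image by default (`scope = "roi"` is available). The
  order — normalize, then wavelet-filter — is the default and is
  configurable (`normalize_first`); the reverse order normalizes each
  band within the ROI instead.
* **Wavelet bank.** One-level *undecimated* separable 3D decomposition,
  so all eight sub-bands (LLL…HHH) keep the grid shape and the ROI mask
  applies unchanged; decimation would break voxel-to-mask
  correspondence. Letter order is (x, y, z). The family is configurable
  (Haar default, Daubechies-2 available) and recorded in provenance;
  boundaries use half-sample symmetric extension. These three choices —
  undecimated, Haar, symmetric — are reproducibility anchors rather than
  claims of optimality.

## The 593-feature catalog

Per band: 14 first-order, 22 GLCM, 16 GLRLM, 13 LBP features; over 9
bands plus 8 shape features computed once: 65 × 9 + 8 = 593. The
per-family split is an engineering choice frozen in
`feature_catalog()` — published 593-item catalogs do not document their
breakdown publicly, so the catalog is config-driven and alternative
splits are possible without touching the extractors.

Numerical conventions worth knowing:

* **Discretization** for GLCM/GLRLM: 32 equal-width bins over the ROI
  intensity range of each band (a common radiomics default; the choice
  is exposed as `n_levels`). A constant ROI becomes a single level,
  flagged, not an error.
* **GLCM/GLRLM aggregation**: matrices at voxel distance 1 along the 13
  unique 3D directions; features computed per direction and averaged,
  which makes them exactly invariant to axis-aligned 90° rotations.
  GLCM matrices are symmetrized and normalized; entropies use log2.
* **LBP**: rotation-invariant uniform patterns (P = 8, R = 1) per axial
  slice, center comparison `neighbor >= center`, pooled into one 10-bin
  histogram plus mean/variance/entropy. For a constant image every pixel
  maps to the all-ones uniform pattern — one bin carries all the mass
  and the histogram entropy is 0.
* **Shape**: surface area comes from marching tetrahedra on a lightly
  smoothed mask indicator (Gaussian, σ = 1.2 voxels, masks ≥ 64 voxels).
  Counting voxel faces overestimates a sphere's area by ~3/2 and would
  make sphericity top out near 0.67; the mesh estimate brings a 64³
  digital ball within 2% of sphericity 1. Volume stays voxel-count
  based. Maximum 3D diameter uses exact pairwise distances up to 1200
  surface voxels and a direction-fan extreme-point approximation above
  that.

## Reliability filter and delta transforms

Test–retest agreement uses ICC(2,1) — two-way random effects, absolute
agreement, single measure — with features retained at ICC > 0.80. In
synthetic mode the "two readers" are two extractions under a one-voxel
random mask translation on a 30-subject retest subset.

The three delta transforms, with Δt in days (PFS is measured in days;
weeks are a config option):

* delta: (f − p)/p — scale-invariant, undefined at p = 0;
* delta-time: (1/Δt)(f − p)/p — halving Δt exactly doubles it;
* delta-log-time: (1/Δt)(log f − log p) — equals delta-time to first
  order in (f − p)/p, requires positive values.

Undefined cells become `NA` with a logged count; downstream selection
median-imputes them rather than dropping subjects.

## Selection, learners, evaluation

Clinical: dummy-encoded covariates → univariate Cox screen (p < 0.1) →
one multivariate fit (keep p < 0.1), after missing-forest imputation
(iterative random forests, median/mode initialization, stop when the
normalized change in imputed values rises, ≤ 10 sweeps; observed cells
never altered).

Radiomic: univariate screen (p < 0.05) → iterative VIF pruning (drop the
largest VIF > 5, recompute) → multivariate fit → keep the top 5 features
by |standardized coefficient| (features are standardized first because
raw Cox coefficients are scale-dependent; rank-5 ties break
lexicographically and are logged) → refit, retain p < 0.1. Two guards
keep the procedure defined on wide inputs: the multivariate stage is
capped at half the event count (best univariate p first, logged), and in
`run_pipeline` a method whose screen retains nothing falls back to its
single best univariate feature, flagged `screen_fallback`, so the
five-method comparison always has five columns. Radiomic stage-1
screening runs per delta method; methods are then compared on the
held-out metric.

Learners behind the uniform `survival_learner()` interface: Cox
(Efron ties), rpart survival tree, ranger random survival forest (risk =
total cumulative hazard), a linear survival *ranking* SVM (squared hinge
on comparable pairs, L2 penalty, active-set Newton iterations — written
for this package since no survival SVM is available in the dependency
set), and xgboost with the Cox objective. The 4-selector × 5-learner
grid is scored by IPCW AUC at the 383-day horizon under 5-fold × 10 CV,
with selection refit inside every training fold.

Evaluation: Harrell's C (ties count ½); cumulative/dynamic time-dependent
AUC with inverse-probability-of-censoring weights from the Kaplan–Meier
censoring distribution (chosen because it handles censoring at fixed
horizons without a model for the censoring mechanism); horizons 6, 9,
12, 15 months at 30.44 days/month, stored in days. Bootstrap comparisons
resample subjects B = 100 times and apply a two-sided paired t-test per
horizon; degenerate replicates are redrawn (≤ 10·B attempts) so B stays
fixed. The Youden threshold maximizes sensitivity + specificity − 1 on
the *training* IPCW ROC at the 383-day horizon (configurable to 12
months); ties take the lower threshold. Log-rank power uses Schoenfeld's
approximation in a two-sided form — the sum of both normal tail
probabilities — so that HR = 1 gives power exactly α = 0.05 and power is
monotone in |log HR| and in the event count.

## The synthetic cohort: what it emulates and what it does not

Defaults mirror a single-center advanced-NSCLC EGFR-TKI study at desk
scale: 226 subjects, 70/30 split, scan interval uniform on 6–16 weeks,
baseline median PFS 383 days, clinical log-hazard effects of the order
reported for such cohorts (N/M staging ~0.25–0.28, platelet 0.31, AST
0.20, total protein −0.17 per SD), laboratory covariates with MCAR
missingness. Where the literature gives no number the value was chosen
once as realistic and is stated here: censoring target 0.30, lab
missingness 0.20, image grids 24³ at 1 mm (images at clinical resolution
would add nothing to the statistical structure while making tests
hours long — the acceptance runs use 226–500 subjects at 16³–24³ and
reduced band catalogs where extraction cost, not statistics, dominates).

Each tumor is an ellipsoid (mean radius uniform on 5–8 mm, per-axis
eccentricity jitter) filled with a Gaussian random field smoothed by a
per-subject kernel (σ ∈ [0.8, 2] voxels). The follow-up image reuses the
*same* field with contrast multiplied by exp(0.25·z), z ~ N(0,1), so
delta features measure change of the same lesion, not fresh noise; z is
the planted signal and enters the latent log-hazard with coefficient
`texture_effect_size`. Survival is Weibull (shape 1 = exponential by
default) on the latent hazard; censoring is uniform on (0, c_max) with
c_max calibrated by bisection to the target rate.

What passing tests therefore show: the pipeline recovers a
texture-change hazard signal end to end through resampling,
normalization, wavelet filtering, extraction, ICC filtering, delta
transformation, selection and Cox fitting, with correct null behavior.
What they do not show: performance on real CT physics (no beam
hardening, dose/kernel variation, registration error, segmentation
disagreement beyond one-voxel jitter), multi-center heterogeneity, or
non-MCAR missingness. One structural note: the observed censoring
*indicator* necessarily correlates with risk under any independent
censoring mechanism (high-risk subjects progress before they can be
censored); independence holds — and is tested — for the censoring-time
draw itself.

## Determinism and degenerate inputs

Every stochastic stage derives a child seed from the master seed via a
fixed offset table (`simulate`, `retest`, `split`, `impute`, `cv`,
`bootstrap`, `benchmark`), so single stages replay identically outside
the full pipeline. Degenerate inputs have defined behavior: constant
ROIs discretize to one level (GLCM correlation defined as 1, LBP entropy
0); zero-variance features drop from the ICC filter with a warning;
p = 0 delta cells become NA; no-event groups flag the log-rank test as
undefined rather than erroring; exact collinearity reports VIF = ∞ and
is eliminated first.
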