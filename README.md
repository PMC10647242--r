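# deltarad

Delta-radiomics survival modeling for paired pre/post-treatment CT.

`deltarad` is an R implementation of a complete delta-radiomics workflow for
predicting progression-free survival (PFS) in oncology imaging studies —
the setting is a lung-adenocarcinoma cohort treated with EGFR tyrosine
kinase inhibitors, imaged once before dosing and once 6–16 weeks after.
The question the package addresses: does the *change* in quantitative
tumor texture between the two scans predict time to progression better
than either scan alone, and does adding it to clinical variables improve a
prognostic Cox model?

## The method

For each subject, the pipeline:

1. **Preprocesses** both CT volumes: trilinear resampling to 1×1×1 mm,
   Z-score intensity normalization (population SD), and a one-level
   undecimated 3D wavelet decomposition giving eight sub-bands
   (LLL, LLH, LHL, LHH, HHL, HLH, HLL, HHH) plus the original image.
2. **Extracts 593 radiomic features** per ROI: 14 first-order, 22 GLCM and
   16 GLRLM texture features (co-occurrence/run-length matrices at
   distance 1, averaged over the 13 unique 3D directions), and 13
   slice-wise rotation-invariant uniform LBP histogram features — each on
   all 9 bands — plus 8 mask shape features.
3. **Filters for reliability**: features must reach test–retest
   ICC(2,1) > 0.80 across repeated segmentations.
4. **Forms delta features.** With pretreatment value *p*, follow-up value
   *f* and inter-scan interval Δt (days):

   - delta: (f − p) / p
   - delta-time: (1/Δt) · (f − p) / p
   - delta-log-time: (1/Δt) · (log f − log p)

   plus the two single-timepoint baselines, giving the five aggregation
   methods that are compared head to head.
5. **Selects features and fits risk models.** Clinical covariates:
   missing-forest imputation, univariate Cox screen at p < 0.1, then a
   multivariate Cox fit retaining p < 0.1. Radiomic features: univariate
   screen at p < 0.05, iterative VIF pruning (threshold 5), multivariate
   fit keeping the top 5 |standardized coefficient| features. A
   4-selector (Kbest / Lasso / Ridge / ElasticNet) × 5-learner (CoxPH,
   survival tree, random survival forest, ranking SVM, gradient-boosted
   Cox) grid is benchmarked under 5-fold × 10 cross-validation at the
   median-PFS horizon (383 days).
6. **Evaluates and stratifies**: Harrell's C-index; IPCW time-dependent
   AUC at 6/9/12/15 months; 100-replicate bootstrap with paired t-tests
   between methods; Youden-index threshold from the training ROC;
   Kaplan–Meier curves, log-rank test and its Schoenfeld power.

Because the clinical imaging data such studies use are private, the
package ships a first-class **synthetic cohort generator**: ellipsoidal
tumors filled with a correlated Gaussian texture field whose
post-treatment contrast shift enters a planted Weibull log-hazard,
clinical covariates with MCAR laboratory missingness, and independent
uniform censoring calibrated to a target rate. Every stage of the
pipeline is exercised and tested against this generator.

## Worked example

```r
library(deltarad)

cfg <- pipeline_config(
  cohort_config = cohort_config(n_subjects = 36, image_shape = c(16L, 16L, 16L),
                                tumor_radius_range_mm = c(4, 6),
                                texture_effect_size = 1.5, seed = 1),
  catalog = feature_catalog(bands = c("Original", "LLL", "HHH"),
                            families = c("firstorder", "glcm", "glrlm"),
                            shape = FALSE),
  icc_subjects = 10, bootstrap_B = 20, seed = 5)
run_pipeline(cfg)
#> <evaluation_report> 36 subjects (25/11 split), 67/156 features past ICC filter
#>   pretreat_only   validation C-index 0.367
#>   follow_only     validation C-index 0.867
#>   delta           validation C-index 0.900
#>   delta_time      validation C-index 0.900
#>   delta_log_time  validation C-index 0.900
#>   clinical+delta  validation C-index 0.867
#>   log-rank p = 0.001827 (power 1.00)
```

The report lists, per aggregation method, the held-out C-index of a Cox
model on that method's selected features: on this (tiny, strongly
planted) cohort the delta methods recover the planted texture-change
hazard best, the follow-up scan (which already reflects the response)
does almost as well, and the pretreatment-only features — uninformative
by construction — hover around chance. `run_pipeline` also
returns horizon AUCs, bootstrap p-values between methods, and the
Youden-threshold Kaplan–Meier stratification of the held-out split.

A command-line front end with the same behavior is installed as
`exec/deltarad` (`deltarad simulate`, `deltarad run`).

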