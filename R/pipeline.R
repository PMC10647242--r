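# End-to-end pipeline driver: preprocess -> extract -> ICC filter -> delta
# -> select -> train -> evaluate -> stratify, with per-stage child seeds
# and persisted intermediate tables.

#' Pipeline configuration with the study defaults
#'
#' Thresholds and schemes default to: univariate/multivariate clinical
#' p < 0.1, radiomic screen p < 0.05, VIF limit 5, top-5 features,
#' ICC > 0.80, 70/30 holdout, 5-fold x 10 cross-validation, B = 100
#' bootstrap replicates, horizons 6/9/12/15 months, scoring horizon 383
#' days (the median PFS).
#'
#' @param cohort_config A [cohort_config()] for `--simulate` runs, or NULL
#'   when reading data from `input_dir`.
#' @param input_dir,output_dir Directories for input data and artifacts
#'   (`output_dir = NULL` keeps everything in memory).
#' @param target_spacing_mm Resampling target, default 1 mm isotropic.
#' @param wavelet_family `"haar"` (default) or `"db2"`.
#' @param normalize_scope `"whole_image"` or `"roi"`.
#' @param normalize_first Normalize before wavelet filtering (default TRUE).
#' @param catalog A [feature_catalog()]; default emits 593 features.
#' @param delta_method Primary delta transform, default `"delta_time"`.
#' @param icc_threshold,icc_subjects Test-retest filter settings (ICC >
#'   0.80 on 30 retest subjects by default).
#' @param train_fraction Holdout training fraction, default 0.7.
#' @param p_clinical,p_radiomic,vif_max,top_k Selection thresholds.
#' @param cv_folds,cv_repeats Cross-validation scheme.
#' @param horizon_days Scoring/Youden horizon (days).
#' @param horizons_days Evaluation horizons (days).
#' @param bootstrap_B Bootstrap replicates for model comparison.
#' @param run_benchmark Also run the 4-selector x 5-learner grid.
#' @param seed Master seed; per-stage child seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_config = NULL,
                            input_dir = NULL, output_dir = NULL,
                            target_spacing_mm = c(1, 1, 1),
                            wavelet_family = "haar",
                            normalize_scope = "whole_image",
                            normalize_first = TRUE,
                            catalog = feature_catalog(),
                            delta_method = "delta_time",
                            icc_threshold = 0.80, icc_subjects = 30L,
                            train_fraction = 0.7,
                            p_clinical = 0.1, p_radiomic = 0.05,
                            vif_max = 5, top_k = 5L,
                            cv_folds = 5L, cv_repeats = 10L,
                            horizon_days = 383,
                            horizons_days = default_horizons_days(),
                            bootstrap_B = 100L,
                            run_benchmark = FALSE,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Preprocess and extract features for one scan
#'
#' Resample to the target spacing, Z-score normalize, build the wavelet
#' bank and extract the catalog features.
#'
#' @param volume,mask The scan and its ROI.
#' @param config A [pipeline_config()] (preprocessing fields are used).
#' @return Named feature vector.
#' @export
extract_subject_features <- function(volume, mask, config = pipeline_config()) {
  rs <- resample_isotropic(volume, mask, config$target_spacing_mm)
  v <- rs$volume; m <- rs$mask
  if (config$normalize_first) v <- znormalize(v, m, config$normalize_scope)
  bank <- wavelet_bank(v, config$wavelet_family)
  if (!config$normalize_first) {
    bank <- structure(lapply(bank, function(b)
      tryCatch(znormalize(b, m, config$normalize_scope),
               error = function(e) b)),
      class = "wavelet_bank", family = attr(bank, "family"))
  }
  extract_all(bank, m, config$catalog)
}

# feature table (both timepoints) for every subject with images
cohort_feature_table <- function(cohort, config) {
  subs <- Filter(function(s) !is.null(s$pre_volume), cohort$subjects)
  if (length(subs) == 0L) stop("cohort has no image data")
  pre <- t(vapply(subs, function(s)
    extract_subject_features(s$pre_volume, s$pre_mask, config),
    numeric(length(catalog_feature_names(config$catalog)))))
  post <- t(vapply(subs, function(s)
    extract_subject_features(s$post_volume, s$post_mask, config),
    numeric(length(catalog_feature_names(config$catalog)))))
  feature_table(pre, post,
                subject_id = vapply(subs, `[[`, "", "subject_id"),
                interval_days = vapply(subs, `[[`, 0, "scan_interval_days"))
}

# translate a mask by one voxel (clipped at the grid edge)
jitter_mask <- function(mask, shift) {
  m <- mask$voxels
  dims <- dim(m)
  out <- array(FALSE, dims)
  src <- lapply(1:3, function(a) axis_range(dims[a], shift[a]))
  dst <- lapply(1:3, function(a) src[[a]] + shift[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  if (!any(out)) m else out
}

#' Synthetic test-retest feature pairs from mask perturbation
#'
#' Emulates two readers by re-extracting pre-treatment features after a
#' one-voxel random translation of each ROI mask, on a retest subset of
#' the cohort.
#'
#' @param cohort A cohort with images.
#' @param config A [pipeline_config()].
#' @param n_retest Number of retest subjects (default 30).
#' @return List with matrices `rater1`, `rater2`.
#' @export
synthetic_retest_pairs <- function(cohort, config, n_retest = 30L) {
  subs <- Filter(function(s) !is.null(s$pre_volume), cohort$subjects)
  n_retest <- min(n_retest, length(subs))
  with_local_seed(stage_seed(config$seed, "retest"), {
    pick <- sample.int(length(subs), n_retest)
    shifts <- matrix(0L, n_retest, 3)
    shifts[cbind(seq_len(n_retest), sample.int(3, n_retest, TRUE))] <-
      sample(c(-1L, 1L), n_retest, TRUE)
    r1 <- t(vapply(subs[pick], function(s)
      extract_subject_features(s$pre_volume, s$pre_mask, config),
      numeric(length(catalog_feature_names(config$catalog)))))
    r2 <- t(vapply(seq_len(n_retest), function(i) {
      s <- subs[[pick[i]]]
      extract_subject_features(
        s$pre_volume, roi_mask(jitter_mask(s$pre_mask, shifts[i, ])), config)
    }, numeric(length(catalog_feature_names(config$catalog)))))
    list(rater1 = r1, rater2 = r2)
  })
}

#' Run the full delta-radiomics pipeline
#'
#' Executes the whole workflow: simulate (or read) the cohort, preprocess
#' and extract features for both timepoints, ICC-filter, compute all five
#' feature aggregation methods (pre-treatment only, follow-up only, delta,
#' time-adjusted delta, time-adjusted log delta), run radiomic selection
#' and Cox training per method on the 70/30 training split, evaluate on
#' the held-out split, fit the clinical and combined models, compare
#' models by bootstrap paired t-tests, and stratify the test set at the
#' training Youden threshold.
#'
#' @param config A [pipeline_config()]. If `config$cohort_config` is set
#'   the cohort is simulated; otherwise it is read from `config$input_dir`.
#' @return An `evaluation_report` list; artifacts are written under
#'   `config$output_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config(cohort_config())) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("input", {
    if (!is.null(config$cohort_config)) {
      cc <- config$cohort_config
      cc$seed <- stage_seed(config$seed, "simulate") %% .Machine$integer.max
      class(cc) <- "cohort_config"
      generate_cohort(cc)
    } else {
      read_cohort(config$input_dir)
    }
  })
  out_dir <- config$output_dir
  persist <- function(obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.data.frame(obj))
      utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    else jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                              auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  ft <- stage("extract", cohort_feature_table(cohort, config))
  persist(ft, "feature_table")

  retained <- stage("icc_filter", {
    pairs <- synthetic_retest_pairs(cohort, config, config$icc_subjects)
    suppressWarnings(
      icc_filter(pairs$rater1, pairs$rater2, config$icc_threshold))
  })
  ft_f <- ft[, c("subject_id", "timepoint", "interval_days", retained),
             drop = FALSE]

  outcomes <- cohort_outcomes(cohort)
  outcomes <- outcomes[match(unique(ft_f$subject_id), outcomes$subject_id), ]
  sp <- stage("split", split_holdout(outcomes, config$train_fraction,
                                     stage_seed(config$seed, "split")))

  methods <- delta_methods()
  method_results <- list()
  risks_test <- list()
  for (m in methods) {
    dt <- stage(paste0("delta_", m), delta_features(ft_f, m))
    stopifnot(identical(dt$subject_id, outcomes$subject_id))
    sel <- stage(paste0("select_", m), select_radiomic(
      dt[sp$train, , drop = FALSE], outcomes[sp$train, ],
      p_stage1 = config$p_radiomic, vif_max = config$vif_max,
      top_k = config$top_k))
    fallback <- FALSE
    if (length(sel$final_features) == 0L) {
      # no feature passed the screen: keep the method in the comparison by
      # fitting on its single best univariate feature, flagged as such
      xall <- as.matrix(dt[sp$train, setdiff(names(dt), "subject_id"),
                           drop = FALSE])
      for (j in seq_len(ncol(xall))) {
        nas <- !is.finite(xall[, j])
        if (any(nas)) xall[nas, j] <- stats::median(xall[, j][!nas])
      }
      sds <- apply(xall, 2, stats::sd)
      xall <- xall[, is.finite(sds) & sds > 0, drop = FALSE]
      uni <- cox_univariate(xall, outcomes$time[sp$train],
                            outcomes$event[sp$train])
      if (all(is.na(uni$p))) {
        method_results[[m]] <- list(selected = character(0))
        next
      }
      sel$final_features <- uni$feature[which.min(uni$p)]
      fallback <- TRUE
    }
    xm <- as.matrix(dt[, sel$final_features, drop = FALSE])
    for (j in seq_len(ncol(xm))) {
      nas <- !is.finite(xm[, j])
      if (any(nas)) xm[nas, j] <- stats::median(xm[, j][!nas])
    }
    mod <- stage(paste0("train_", m),
                 fit_coxph(xm[sp$train, , drop = FALSE],
                           outcomes[sp$train, ]))
    risk_tr <- predict(mod, xm[sp$train, , drop = FALSE])
    risk_te <- predict(mod, xm[sp$test, , drop = FALSE])
    risks_test[[m]] <- risk_te
    method_results[[m]] <- list(
      selected = sel$final_features,
      screen_fallback = fallback,
      model = mod,
      train = evaluate_risk(risk_tr, outcomes$time[sp$train],
                            outcomes$event[sp$train], config$horizons_days),
      validation = evaluate_risk(risk_te, outcomes$time[sp$test],
                                 outcomes$event[sp$test],
                                 config$horizons_days))
  }

  # clinical model: impute, staged selection, Cox fit
  clin <- cohort_clinical(cohort)
  clin_imp <- stage("impute", impute_missing_forest(
    clin[, setdiff(names(clin), "subject_id"), drop = FALSE],
    seed = stage_seed(config$seed, "impute")))
  xc <- encode_clinical(clin_imp)
  sel_c <- stage("select_clinical", select_clinical(
    clin_imp[sp$train, , drop = FALSE], outcomes[sp$train, ],
    config$p_clinical, config$p_clinical))
  clinical_result <- NULL
  risk_clin_te <- NULL
  if (length(sel_c$final_features) > 0L) {
    xcm <- xc[, sel_c$final_features, drop = FALSE]
    mod_c <- fit_coxph(xcm[sp$train, , drop = FALSE], outcomes[sp$train, ])
    risk_clin_te <- predict(mod_c, xcm[sp$test, , drop = FALSE])
    clinical_result <- list(
      selected = sel_c$final_features, model = mod_c,
      validation = evaluate_risk(risk_clin_te, outcomes$time[sp$test],
                                 outcomes$event[sp$test],
                                 config$horizons_days))
  }

  # combined model: joint Cox fit on selected clinical + primary delta features
  primary <- config$delta_method
  combined_result <- NULL
  risk_comb_te <- NULL
  if (!is.null(clinical_result) &&
      length(method_results[[primary]]$selected) > 0L) {
    dtp <- delta_features(ft_f, primary)
    xr <- as.matrix(dtp[, method_results[[primary]]$selected, drop = FALSE])
    for (j in seq_len(ncol(xr))) {
      nas <- !is.finite(xr[, j])
      if (any(nas)) xr[nas, j] <- stats::median(xr[, j][!nas])
    }
    xu <- cbind(xr, xc[, sel_c$final_features, drop = FALSE])
    mod_u <- stage("train_combined",
                   fit_coxph(xu[sp$train, , drop = FALSE],
                             outcomes[sp$train, ]))
    risk_comb_tr <- predict(mod_u, xu[sp$train, , drop = FALSE])
    risk_comb_te <- predict(mod_u, xu[sp$test, , drop = FALSE])
    combined_result <- list(
      model = mod_u,
      validation = evaluate_risk(risk_comb_te, outcomes$time[sp$test],
                                 outcomes$event[sp$test],
                                 config$horizons_days))
  }

  # bootstrap comparisons against the primary delta method
  comparisons <- list()
  if (!is.null(risks_test[[primary]])) {
    for (m in setdiff(names(risks_test), primary)) {
      comparisons[[paste0(m, "_vs_", primary)]] <- stage("bootstrap",
        bootstrap_compare(risks_test[[m]], risks_test[[primary]],
                          outcomes$time[sp$test], outcomes$event[sp$test],
                          config$horizons_days, config$bootstrap_B,
                          config$seed)$p_values)
    }
    if (!is.null(risk_comb_te) && !is.null(risk_clin_te)) {
      comparisons[["clinical_vs_combined"]] <-
        bootstrap_compare(risk_clin_te, risk_comb_te, outcomes$time[sp$test],
                          outcomes$event[sp$test], config$horizons_days,
                          config$bootstrap_B, config$seed)$p_values
    }
  }

  # Youden stratification of the test set, threshold from training only
  stratification <- NULL
  strat_risk_tr <- NULL; strat_risk_te <- NULL
  if (!is.null(risk_comb_te)) {
    strat_risk_tr <- risk_comb_tr; strat_risk_te <- risk_comb_te
  } else if (!is.null(risks_test[[primary]])) {
    mr <- method_results[[primary]]
    dtp <- delta_features(ft_f, primary)
    xr <- as.matrix(dtp[, mr$selected, drop = FALSE])
    strat_risk_tr <- predict(mr$model, xr[sp$train, , drop = FALSE])
    strat_risk_te <- risks_test[[primary]]
  }
  if (!is.null(strat_risk_te)) {
    thr <- stage("stratify", youden_threshold(
      strat_risk_tr, outcomes$time[sp$train], outcomes$event[sp$train],
      config$horizon_days))
    grp <- ifelse(strat_risk_te > thr, "high", "low")
    stratification <- if (length(unique(grp)) == 2L) {
      c(list(threshold = as.numeric(thr)),
        km_logrank(grp, outcomes$time[sp$test], outcomes$event[sp$test]))
    } else list(threshold = as.numeric(thr), logrank_defined = FALSE)
  }

  benchmark <- NULL
  if (isTRUE(config$run_benchmark)) {
    dtp <- delta_features(ft_f, primary)
    benchmark <- stage("benchmark", benchmark_selectors(
      dtp[sp$train, , drop = FALSE], outcomes[sp$train, ],
      k_features = config$top_k, k = config$cv_folds,
      repeats = config$cv_repeats, horizon_days = config$horizon_days,
      seed = config$seed))
  }

  report <- structure(list(
    n_subjects = nrow(outcomes),
    n_features_extracted = length(catalog_feature_names(config$catalog)),
    n_features_retained = length(retained),
    split = list(train = length(sp$train), test = length(sp$test)),
    methods = method_results,
    clinical = clinical_result,
    combined = combined_result,
    comparisons = comparisons,
    stratification = stratification,
    benchmark = benchmark,
    provenance = list(seed = config$seed,
                      delta_method = primary,
                      wavelet_family = config$wavelet_family,
                      horizons_days = config$horizons_days,
                      r_version = as.character(getRversion()))
  ), class = "evaluation_report")
  if (!is.null(out_dir)) {
    persist(list(
      methods = lapply(method_results, function(m)
        m[setdiff(names(m), "model")]),
      clinical = clinical_result[setdiff(names(clinical_result), "model")],
      combined = combined_result[setdiff(names(combined_result), "model")],
      comparisons = comparisons,
      stratification = stratification["threshold" != names(stratification) |
                                        TRUE],
      provenance = report$provenance), "report")
    if (!is.null(stratification$km_curves))
      persist(stratification$km_curves, "km_curves")
  }
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$n_subjects, " subjects (",
      x$split$train, "/", x$split$test, " split), ",
      x$n_features_retained, "/", x$n_features_extracted,
      " features past ICC filter\n", sep = "")
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    if (is.null(r$validation)) next
    cat(sprintf("  %-15s validation C-index %.3f\n", m, r$validation$c_index))
  }
  if (!is.null(x$combined))
    cat(sprintf("  %-15s validation C-index %.3f\n", "clinical+delta",
                x$combined$validation$c_index))
  if (!is.null(x$stratification$logrank_p))
    cat(sprintf("  log-rank p = %.4g (power %.2f)\n",
                x$stratification$logrank_p, x$stratification$power))
  invisible(x)
}
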