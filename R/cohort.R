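# Synthetic paired-CT cohort generator. Each subject carries an ellipsoidal
# tumor filled with a correlated Gaussian texture field; the follow-up scan
# reuses the same field with a per-subject contrast shift that enters the
# latent log-hazard, so delta features of the same lesion carry a planted,
# recoverable survival signal. Survival times are Weibull on the latent
# hazard with independent uniform censoring calibrated to a target rate.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror a single-center advanced-NSCLC EGFR-TKI cohort: 226
#' subjects, scan interval 6-16 weeks, baseline median progression-free
#' survival 383 days, clinical log-hazard effects of the order reported for
#' N/M staging, platelet count, AST and total protein, 30% censoring and
#' 20% missingness in the laboratory covariates.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param image_shape Voxel grid triple for each volume.
#' @param voxel_spacing_mm Positive spacing triple (mm).
#' @param tumor_radius_range_mm Interval of mean tumor radii (mm).
#' @param texture_effect_size Log-hazard coefficient on the standardized
#'   planted texture-change signal.
#' @param clinical_effect_sizes Named log-hazard coefficients for the
#'   clinical covariates `n_stage`, `m_stage`, `platelet`, `ast`,
#'   `total_protein` (applied to standardized numeric codes).
#' @param censor_rate_target Target fraction of censored subjects in [0, 1].
#' @param interval_weeks_range Pre/post scan interval range, inside [6, 16]
#'   weeks.
#' @param missing_rate MCAR missingness fraction for laboratory covariates.
#' @param weibull_shape Weibull shape of the survival model (1 = exponential).
#' @param median_pfs_days Baseline median survival at zero log-hazard.
#' @param generate_images Generate image volumes/masks (disable for fast
#'   covariate-only simulations).
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 226L,
                          image_shape = c(24L, 24L, 24L),
                          voxel_spacing_mm = c(1, 1, 1),
                          tumor_radius_range_mm = c(5, 8),
                          texture_effect_size = 1.0,
                          clinical_effect_sizes = c(
                            n_stage = 0.25, m_stage = 0.28, platelet = 0.31,
                            ast = 0.20, total_protein = -0.17),
                          censor_rate_target = 0.30,
                          interval_weeks_range = c(6, 16),
                          missing_rate = 0.20,
                          weibull_shape = 1,
                          median_pfs_days = 383,
                          generate_images = TRUE,
                          seed = 1L) {
  if (n_subjects < 2L) stop("configuration error: n_subjects must be >= 2")
  if (any(image_shape <= 0) || any(voxel_spacing_mm <= 0))
    stop("configuration error: non-positive shape or spacing")
  if (interval_weeks_range[1] < 6 || interval_weeks_range[2] > 16 ||
      interval_weeks_range[1] > interval_weeks_range[2])
    stop("configuration error: interval range must lie inside [6, 16] weeks")
  if (censor_rate_target < 0 || censor_rate_target >= 1)
    stop("configuration error: censor_rate_target must be in [0, 1)")
  if (missing_rate < 0 || missing_rate > 1)
    stop("configuration error: missing_rate must be in [0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects),
    image_shape = as.integer(image_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    tumor_radius_range_mm = as.numeric(tumor_radius_range_mm),
    texture_effect_size = texture_effect_size,
    clinical_effect_sizes = clinical_effect_sizes,
    censor_rate_target = censor_rate_target,
    interval_weeks_range = as.numeric(interval_weeks_range),
    missing_rate = missing_rate,
    weibull_shape = weibull_shape,
    median_pfs_days = median_pfs_days,
    generate_images = isTRUE(generate_images),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# ellipsoid mask centered near the grid center
ellipsoid_mask <- function(dims, center, semi_axes_vox) {
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - center[a]) / semi_axes_vox[a])^2)
  field <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  array(field <= 1, dims)
}

simulate_subject_images <- function(config, radius_mm, sigma_field, contrast_pre,
                                    contrast_post) {
  dims <- config$image_shape
  sp <- config$voxel_spacing_mm
  center <- dims / 2 + stats::runif(3, -0.5, 0.5)
  semi_mm <- radius_mm * stats::runif(3, 0.85, 1.15)
  mask_arr <- ellipsoid_mask(dims, center, semi_mm / sp)
  if (!any(mask_arr)) mask_arr[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                               ceiling(dims[3] / 2)] <- TRUE
  field <- gaussian_smooth3d(array(stats::rnorm(prod(dims)), dims), sigma_field)
  field <- (field - mean(field)) / pop_sd(field)
  bg_pre <- array(stats::rnorm(prod(dims), sd = 0.2), dims)
  bg_post <- array(stats::rnorm(prod(dims), sd = 0.2), dims)
  pre <- bg_pre; post <- bg_post
  pre[mask_arr] <- 1 + contrast_pre * field[mask_arr] + bg_pre[mask_arr]
  post[mask_arr] <- 1 + contrast_post * field[mask_arr] + bg_post[mask_arr]
  list(
    pre_volume = image_volume(pre, sp), post_volume = image_volume(post, sp),
    pre_mask = roi_mask(mask_arr), post_mask = roi_mask(mask_arr)
  )
}

simulate_clinical <- function(n) {
  n_stage <- sample(c("N0", "N1", "N2", "N3"), n, replace = TRUE,
                    prob = c(0.27, 0.08, 0.27, 0.38))
  m_stage <- sample(c("M0", "M1a", "M1b", "M1c"), n, replace = TRUE,
                    prob = c(0.04, 0.25, 0.20, 0.51))
  data.frame(
    n_stage = n_stage,
    m_stage = m_stage,
    ecog = sample(c("0", "1", "2", ">2"), n, replace = TRUE,
                  prob = c(0.35, 0.53, 0.07, 0.05)),
    gender = sample(c("female", "male"), n, replace = TRUE,
                    prob = c(0.6, 0.4)),
    smoking = sample(c("never", "smoker"), n, replace = TRUE,
                     prob = c(0.76, 0.24)),
    histology = sample(c("adenocarcinoma", "squamous", "other"), n,
                       replace = TRUE, prob = c(0.96, 0.02, 0.02)),
    tki = sample(c("gefitinib", "erlotinib", "afatinib"), n, replace = TRUE,
                 prob = c(0.17, 0.30, 0.53)),
    age = round(stats::rnorm(n, 63, 11), 1),
    platelet = round(stats::rlnorm(n, log(269000), 0.25)),
    ast = round(stats::rlnorm(n, log(23), 0.35), 1),
    total_protein = round(stats::rnorm(n, 7.1, 0.35), 2),
    stringsAsFactors = FALSE
  )
}

standardize_col <- function(x) {
  s <- stats::sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

clinical_linear_predictor <- function(clin, effects) {
  codes <- list(
    n_stage = as.numeric(factor(clin$n_stage,
                                levels = c("N0", "N1", "N2", "N3"))) - 1,
    m_stage = as.numeric(factor(clin$m_stage,
                                levels = c("M0", "M1a", "M1b", "M1c"))) - 1,
    platelet = clin$platelet,
    ast = clin$ast,
    total_protein = clin$total_protein
  )
  lp <- rep(0, nrow(clin))
  for (nm in names(effects)) {
    if (!nm %in% names(codes)) stop("unknown clinical effect '", nm, "'")
    lp <- lp + effects[[nm]] * standardize_col(codes[[nm]])
  }
  lp
}

# calibrate the uniform censoring upper bound so that P(C < T) hits the
# target: censored fraction under C ~ U(0, cmax) is mean(pmin(T, cmax)/cmax)
calibrate_censoring <- function(times, target) {
  if (target <= 0) return(Inf)
  frac <- function(cmax) mean(pmin(times, cmax) / cmax)
  lo <- min(times) * 1e-3
  hi <- max(times) * 2
  while (frac(hi) > target) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (frac(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic paired-scan cohort
#'
#' Deterministic given the configuration (which includes the seed). Each
#' subject receives paired pre/post volumes and masks (unless
#' `generate_images = FALSE`), a clinical record with MCAR laboratory
#' missingness, a right-censored survival outcome and the latent
#' log-hazard (`true_risk`) it was drawn from.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list of subjects, the
#'   config, and a `ground_truth` list (planted coefficients, per-subject
#'   texture-change signal and latent risks).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    n <- config$n_subjects
    clin <- simulate_clinical(n)
    delta_z <- stats::rnorm(n)                       # planted texture signal
    lp_clin <- clinical_linear_predictor(clin, config$clinical_effect_sizes)
    lp <- config$texture_effect_size * delta_z + lp_clin

    k <- config$weibull_shape
    lambda <- config$median_pfs_days / log(2)^(1 / k)
    u <- stats::runif(n)
    t_event <- lambda * (-log(u) / exp(lp))^(1 / k)
    cmax <- calibrate_censoring(t_event, config$censor_rate_target)
    c_time <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
    time <- pmax(pmin(t_event, c_time), 0.5)
    event <- as.integer(t_event <= c_time)

    interval_days <- stats::runif(n, config$interval_weeks_range[1] * 7,
                                  config$interval_weeks_range[2] * 7)
    scan_date_pre <- as.Date("2018-01-01") +
      sample.int(540L, n, replace = TRUE)

    # MCAR lab missingness
    clin_missing <- clin
    for (lab in c("platelet", "ast", "total_protein")) {
      miss <- stats::runif(n) < config$missing_rate
      clin_missing[[lab]][miss] <- NA
    }

    subjects <- vector("list", n)
    radius <- stats::runif(n, config$tumor_radius_range_mm[1],
                           config$tumor_radius_range_mm[2])
    for (i in seq_len(n)) {
      imgs <- NULL
      if (config$generate_images) {
        sigma_field <- stats::runif(1, 0.8, 2.0)
        contrast_pre <- 1
        contrast_post <- exp(0.25 * delta_z[i])
        imgs <- simulate_subject_images(config, radius[i], sigma_field,
                                        contrast_pre, contrast_post)
      }
      subjects[[i]] <- structure(c(
        list(
          subject_id = sprintf("S%04d", i),
          scan_interval_days = interval_days[i],
          scan_date_pre = scan_date_pre[i],
          scan_date_post = scan_date_pre[i] + round(interval_days[i]),
          clinical = clin_missing[i, , drop = FALSE],
          outcome = list(time = time[i], event = event[i]),
          true_risk = lp[i]
        ),
        imgs
      ), class = "synthetic_subject")
    }
    structure(list(
      subjects = subjects,
      config = config,
      ground_truth = list(
        texture_effect_size = config$texture_effect_size,
        clinical_effect_sizes = config$clinical_effect_sizes,
        delta_signal = delta_z,
        true_risk = lp,
        censor_time = c_time,
        clinical_complete = clin
      )
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  oc <- cohort_outcomes(x)
  cat("<synthetic_cohort> ", length(x$subjects), " subjects, ",
      sum(oc$event), " events (", round(100 * (1 - mean(oc$event)), 1),
      "% censored), images: ", x$config$generate_images, "\n", sep = "")
  invisible(x)
}

#' Survival outcomes of a cohort as a data frame
#' @param cohort A `synthetic_cohort`.
#' @return Data frame with `subject_id`, `time`, `event`.
#' @export
cohort_outcomes <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    time = vapply(cohort$subjects, function(s) s$outcome$time, 0),
    event = vapply(cohort$subjects, function(s) s$outcome$event, 0L),
    stringsAsFactors = FALSE
  )
}

#' Clinical records of a cohort as a data frame (with missingness)
#' @param cohort A `synthetic_cohort`.
#' @return Data frame, one row per subject.
#' @export
cohort_clinical <- function(cohort) {
  out <- do.call(rbind, lapply(cohort$subjects, `[[`, "clinical"))
  out <- cbind(subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Report the planted ground-truth effects of a synthetic cohort
#'
#' Returns the true coefficients and per-subject latent risks so recovery
#' tests can compare fitted models against the generating mechanism.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @return List with `coefficients` (texture + clinical), `delta_signal`
#'   and `true_risk`.
#' @export
planted_signal_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  gt <- cohort$ground_truth
  list(
    coefficients = c(texture = gt$texture_effect_size,
                     gt$clinical_effect_sizes),
    delta_signal = gt$delta_signal,
    true_risk = gt$true_risk
  )
}
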