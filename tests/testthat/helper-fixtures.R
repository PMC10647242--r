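# Shared fixtures: small geometric phantoms and cached synthetic cohorts.

sphere_mask <- function(n, r) {
  cx <- seq_len(n) - (n + 1) / 2
  roi_mask(array(outer(outer(cx^2, cx^2, "+"), cx^2, "+") <= r^2, c(n, n, n)))
}

random_volume <- function(dims, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  image_volume(array(rnorm(prod(dims)), dims), spacing)
}

# integer phantom for matrix-feature oracles
integer_phantom <- function(dims, n_levels, seed = 1) {
  set.seed(seed)
  arr <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  list(volume = image_volume(arr + 0, c(1, 1, 1)),
       mask = roi_mask(array(TRUE, dims)))
}

# simple censored survival draw on a given log-hazard
draw_surv <- function(lp, seed = 1, scale = 383, censor_max = 1200) {
  set.seed(seed)
  n <- length(lp)
  t_ev <- scale / log(2) * (-log(runif(n)) / exp(lp))
  cc <- runif(n, 0, censor_max)
  data.frame(time = pmax(pmin(t_ev, cc), 0.5), event = as.integer(t_ev <= cc))
}

# memoised small image cohort shared by pipeline-level tests
.fixture_env <- new.env(parent = emptyenv())
small_image_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(cohort_config(
      n_subjects = 36, image_shape = c(16L, 16L, 16L),
      tumor_radius_range_mm = c(4, 6), texture_effect_size = 1.5, seed = 42))
  }
  .fixture_env$cohort
}

reduced_catalog <- function() {
  feature_catalog(bands = c("Original", "LLL", "HHH"),
                  families = c("firstorder", "glcm", "glrlm"), shape = FALSE)
}
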