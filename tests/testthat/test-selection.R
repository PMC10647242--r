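# Missing-forest imputation, VIF, staged clinical/radiomic selection and
# the selector benchmark grid.

test_that("imputation returns complete tables untouched and fills constants", {
  df <- data.frame(a = 1:5, b = letters[1:5])
  expect_identical(impute_missing_forest(df), df)

  df2 <- data.frame(a = c(3, 3, NA, 3, 3), b = rnorm(5))
  out <- impute_missing_forest(df2, seed = 1)
  expect_equal(out$a[3], 3)
  expect_identical(out$b, df2$b)
  expect_error(impute_missing_forest(data.frame(a = c(NA, NA))), "schema")
})

test_that("forest imputation beats median imputation on correlated columns", {
  set.seed(14)
  n <- 200
  x <- rnorm(n)
  y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)   # r = 0.9
  truth <- y
  miss <- sample.int(n, 40)                  # 20% MCAR
  df <- data.frame(x = x, y = replace(y, miss, NA))
  imp <- impute_missing_forest(df, seed = 2)
  rmse_rf <- sqrt(mean((imp$y[miss] - truth[miss])^2))
  rmse_med <- sqrt(mean((median(df$y, na.rm = TRUE) - truth[miss])^2))
  expect_lt(rmse_rf, rmse_med)
  expect_identical(imp$y[-miss], y[-miss])   # observed cells untouched
})

test_that("VIF matches the closed form and flags exact collinearity", {
  set.seed(6)
  n <- 100
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- 0.8 * scale(x1)[, 1] + 0.6 * rnorm(n)
  x <- cbind(a = x1, b = x2, c = x3)
  v <- vif(x)
  # oracle: 1 / (1 - R^2) via lm() for each column
  for (j in 1:3) {
    r2 <- summary(lm(x[, j] ~ x[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-9)
  }
  # orthonormal design: all VIF = 1 (up to the incidental correlation an
  # uncentered orthonormal basis has with the intercept)
  q <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  colnames(q) <- c("q1", "q2", "q3")
  expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-4)
  # duplicated column: infinite VIF
  xx <- cbind(u = x1, v = x1)
  expect_true(all(is.infinite(vif(xx))))
})

test_that("a covariate equal to the true log-hazard is retained by the clinical screen", {
  set.seed(30)
  n <- 300
  lp <- rnorm(n)
  oc <- draw_surv(lp, seed = 31)
  rec <- data.frame(signal = lp, noise1 = rnorm(n), noise2 = rnorm(n))
  sel <- select_clinical(rec, oc)
  expect_true("signal" %in% sel$final_features)
  expect_true(all(c("stage", "criterion", "features_in", "features_out")
                  %in% names(sel$stage_log)))
})

test_that("pure-noise covariates are retained at about the nominal rate", {
  rates <- sapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 300
    oc <- draw_surv(rep(0, n), seed = 200 + s)
    x <- matrix(rnorm(n * 50), n, 50,
                dimnames = list(NULL, paste0("f", 1:50)))
    uni <- suppressWarnings(
      deltarad:::cox_univariate(x, oc$time, oc$event))
    mean(uni$p < 0.1, na.rm = TRUE)
  })
  expect_lt(abs(mean(rates) - 0.1), 0.05)
})

test_that("an empty stage-1 survivor set yields an empty result, not an error", {
  set.seed(40)
  n <- 120
  oc <- draw_surv(rep(0, n), seed = 41)
  # constant covariates can never pass the screen
  rec <- data.frame(c1 = rep(1, n), c2 = rep(2, n))
  sel <- suppressWarnings(select_clinical(rec, oc))
  expect_length(sel$final_features, 0)
})

test_that("duplicated radiomic columns are eliminated at the VIF stage", {
  set.seed(50)
  n <- 150
  z <- rnorm(n)
  oc <- draw_surv(z, seed = 51)
  dt <- data.frame(subject_id = paste0("s", 1:n),
                   fA = z, fB = z, fC = rnorm(n))
  sel <- select_radiomic(dt, oc)
  expect_false(all(c("fA", "fB") %in% sel$final_features))
  expect_true(any(c("fA", "fB") %in% sel$final_features))
})

test_that("planted radiomic effects rank in the top five in most seeds", {
  hits <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 400
    x <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, sprintf("f%02d", 1:20)))
    lp <- 0.8 * x[, 1] + 0.8 * x[, 2] + 0.8 * x[, 3]
    oc <- draw_surv(lp, seed = 2000 + s)
    sel <- select_radiomic(data.frame(x), oc)
    all(c("f01", "f02", "f03") %in% sel$final_features)
  })
  expect_gte(mean(hits), 0.80)
})

test_that("VIF pruning never increases the maximum VIF of the surviving set", {
  set.seed(60)
  n <- 120
  base <- matrix(rnorm(n * 4), n, 4)
  x <- cbind(base,
             base[, 1] + 0.2 * rnorm(n),
             base[, 2] + 0.2 * rnorm(n))
  colnames(x) <- paste0("g", 1:6)
  max_before <- max(vif(x))
  kept <- deltarad:::prune_vif(x, 5)
  expect_true(length(kept) >= 2)
  expect_lte(max(vif(x[, kept, drop = FALSE])), max_before)
  expect_lte(max(vif(x[, kept, drop = FALSE])), 5)
})

test_that("Kbest picks the k features with the largest univariate score", {
  set.seed(70)
  n <- 200
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  lp <- 1.2 * x[, 1] + 1.0 * x[, 2]
  oc <- draw_surv(lp, seed = 71)
  sel <- select_k_features(x, oc, "kbest", k = 2)
  expect_setequal(sel, c("f1", "f2"))
  for (s in c("lasso", "ridge", "elasticnet"))
    expect_length(select_k_features(x, oc, s, k = 5), 5)
})

test_that("the benchmark grid has the 4 x 5 shape and sane null behavior", {
  set.seed(80)
  n <- 120
  x <- data.frame(matrix(rnorm(n * 10), n, 10))
  names(x) <- paste0("f", 1:10)
  oc <- draw_surv(0.9 * x$f1, seed = 81)
  bm <- benchmark_selectors(x, oc, k_features = 3, k = 3, repeats = 1,
                            horizon_days = 383, seed = 5)
  expect_equal(nrow(bm$grid), 4 * 5)
  expect_setequal(unique(bm$grid$selector),
                  c("kbest", "lasso", "ridge", "elasticnet"))
  expect_setequal(unique(bm$grid$learner), survival_learner_names())
  expect_true(all(bm$grid$mean_auc >= 0 & bm$grid$mean_auc <= 1, na.rm = TRUE))
  expect_equal(nrow(bm$best), 1)
})
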