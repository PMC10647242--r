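# Missing-forest imputation, staged Cox feature selection for clinical and
# radiomic variables, variance-inflation pruning, and the selector-by-learner
# benchmark grid.

#' Iterative random-forest ("missing forest") imputation
#'
#' Initializes missing cells with column medians (numeric) or modes
#' (categorical), then iteratively regresses each incomplete column on all
#' others with a random forest, re-imputing its missing cells, until the
#' normalized change in imputed values stops decreasing or `max_iter`
#' iterations. Observed cells are never altered.
#'
#' @param table Data frame; every column must have at least one observed
#'   value. Character columns are treated as categorical.
#' @param seed Integer seed for the forests.
#' @param max_iter Maximum sweeps over the incomplete columns (default 10).
#' @param num_trees Trees per forest (default 100).
#' @return The completed data frame (same classes as the input).
#' @export
impute_missing_forest <- function(table, seed = 1L, max_iter = 10L,
                                  num_trees = 100L) {
  stopifnot(is.data.frame(table))
  df <- table
  was_char <- vapply(df, is.character, TRUE)
  for (j in which(was_char)) df[[j]] <- factor(df[[j]])
  miss <- lapply(df, is.na)
  n_miss <- vapply(miss, sum, 0L)
  if (any(n_miss == nrow(df)))
    stop("schema error: column(s) entirely missing: ",
         paste(names(df)[n_miss == nrow(df)], collapse = ", "))
  if (all(n_miss == 0L)) return(table)

  # median/mode initialization
  for (j in names(df)[n_miss > 0L]) {
    if (is.numeric(df[[j]])) {
      df[[j]][miss[[j]]] <- stats::median(df[[j]], na.rm = TRUE)
    } else {
      tab <- table(df[[j]])
      df[[j]][miss[[j]]] <- names(tab)[which.max(tab)]
    }
  }

  cols <- names(df)[order(n_miss)]
  cols <- cols[n_miss[cols] > 0L]
  prev_df <- df
  prev_change <- Inf
  with_local_seed(seed, {
    for (it in seq_len(max_iter)) {
      for (j in cols) {
        obs <- !miss[[j]]
        rf <- ranger::ranger(
          x = df[obs, setdiff(names(df), j), drop = FALSE],
          y = df[[j]][obs], num.trees = num_trees,
          respect.unordered.factors = "order", num.threads = 1,
          seed = stage_seed(seed, "impute") + it
        )
        pred <- stats::predict(rf,
          data = df[miss[[j]], setdiff(names(df), j), drop = FALSE])$predictions
        df[[j]][miss[[j]]] <- pred
      }
      # missForest stopping rule: stop when the change increases
      num_cols <- cols[vapply(df[cols], is.numeric, TRUE)]
      cat_cols <- setdiff(cols, num_cols)
      ch_num <- 0
      if (length(num_cols)) {
        newv <- unlist(lapply(num_cols, function(j) df[[j]][miss[[j]]]))
        oldv <- unlist(lapply(num_cols, function(j) prev_df[[j]][miss[[j]]]))
        denom <- sum(newv^2)
        ch_num <- if (denom > 0) sum((newv - oldv)^2) / denom else 0
      }
      ch_cat <- 0
      if (length(cat_cols)) {
        newv <- unlist(lapply(cat_cols, function(j) as.character(df[[j]][miss[[j]]])))
        oldv <- unlist(lapply(cat_cols, function(j) as.character(prev_df[[j]][miss[[j]]])))
        ch_cat <- mean(newv != oldv)
      }
      change <- ch_num + ch_cat
      if (change >= prev_change) { df <- prev_df; break }
      prev_change <- change
      prev_df <- df
    }
  })
  for (j in which(was_char)) df[[j]] <- as.character(df[[j]])
  df
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the ordinary least-squares regression of
#' feature j on the remaining features; exact collinearity is reported as
#' `Inf`.
#'
#' @param x Numeric matrix or data frame with >= 2 columns and more rows
#'   than columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(p >= 2L, nrow(x) > p)
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    rss <- sum(fit$residuals^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

# univariate Cox screen of each column; returns data.frame(feature, coef, p)
cox_univariate <- function(x, time, event) {
  res <- lapply(colnames(x), function(f) {
    v <- x[, f]
    ok <- is.finite(v)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0)
      return(data.frame(feature = f, coef = NA_real_, p = NA_real_))
    fit <- tryCatch(
      survival::coxph(survival::Surv(time[ok], event[ok]) ~ v[ok],
                      ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit))
      return(data.frame(feature = f, coef = NA_real_, p = NA_real_))
    s <- summary(fit)$coefficients
    data.frame(feature = f, coef = s[1, "coef"],
               p = s[1, "Pr(>|z|)"])
  })
  do.call(rbind, res)
}

stage_entry <- function(stage, criterion, n_in, n_out) {
  data.frame(stage = stage, criterion = criterion,
             features_in = n_in, features_out = n_out,
             stringsAsFactors = FALSE)
}

#' Dummy-encode a clinical record table
#'
#' Categorical columns become treatment-coded indicator columns (reference
#' level dropped); numeric columns pass through.
#'
#' @param records Data frame of covariates (a `subject_id` column, if
#'   present, is dropped).
#' @return Numeric matrix.
#' @export
encode_clinical <- function(records) {
  df <- records[, setdiff(names(records), "subject_id"), drop = FALSE]
  for (j in names(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Two-stage clinical feature selection
#'
#' Dummy-encodes categorical covariates, screens each encoded variable with
#' a univariate Cox proportional-hazards fit at `p_stage1`, then fits one
#' multivariate Cox model on the survivors and keeps variables at
#' `p_stage2` (both thresholds default 0.1). Non-convergent univariate fits
#' are excluded with a log entry.
#'
#' @param records Data frame of clinical covariates (complete; impute
#'   first with [impute_missing_forest()]).
#' @param outcomes Data frame with `time` and `event` (>= 10 events).
#' @return A `selection_result`: `stage_log`, `final_features`,
#'   `coefficients` (from the final refit).
#' @export
select_clinical <- function(records, outcomes, p_stage1 = 0.1,
                            p_stage2 = 0.1) {
  if (sum(outcomes$event) < 10L) stop("need at least 10 events")
  x <- encode_clinical(records)
  log_ <- stage_entry("encode", "dummy encoding", ncol(records), ncol(x))
  uni <- cox_univariate(x, outcomes$time, outcomes$event)
  keep1 <- uni$feature[!is.na(uni$p) & uni$p < p_stage1]
  log_ <- rbind(log_, stage_entry("univariate", paste0("p<", p_stage1),
                                  ncol(x), length(keep1)))
  if (length(keep1) == 0L) {
    return(structure(list(stage_log = log_, final_features = character(0),
                          coefficients = numeric(0)),
                     class = "selection_result"))
  }
  df <- data.frame(x[, keep1, drop = FALSE], check.names = FALSE)
  fit <- survival::coxph(
    survival::Surv(outcomes$time, outcomes$event) ~ .,
    data = df, ties = "efron")
  s <- summary(fit)$coefficients
  keep2 <- rownames(s)[s[, "Pr(>|z|)"] < p_stage2]
  keep2 <- gsub("^`|`$", "", keep2)
  log_ <- rbind(log_, stage_entry("multivariate", paste0("p<", p_stage2),
                                  length(keep1), length(keep2)))
  coefs <- numeric(0)
  if (length(keep2) > 0L) {
    refit <- survival::coxph(
      survival::Surv(outcomes$time, outcomes$event) ~ .,
      data = data.frame(x[, keep2, drop = FALSE], check.names = FALSE),
      ties = "efron")
    coefs <- stats::coef(refit)
    names(coefs) <- keep2
  }
  structure(list(stage_log = log_, final_features = keep2,
                 coefficients = coefs),
            class = "selection_result")
}

# iterative VIF pruning: recompute after each removal, drop the largest
# VIF while it exceeds the threshold
prune_vif <- function(x, threshold = 5) {
  feats <- colnames(x)
  while (length(feats) >= 2L && nrow(x) > length(feats)) {
    v <- vif(x[, feats, drop = FALSE])
    if (max(v) <= threshold) break
    feats <- setdiff(feats, names(which.max(v)))
  }
  feats
}

#' Three-stage radiomic feature selection
#'
#' Stage 1: univariate Cox screen at `p_stage1` (default 0.05) on
#' standardized features. Stage 2: iterative variance-inflation pruning,
#' removing the largest VIF above `vif_max` (default 5) and recomputing
#' until all survivors are below it. Stage 3: one multivariate Cox fit;
#' the `top_k` (default 5) features with the largest absolute standardized
#' coefficients are kept (rank-5 ties broken lexicographically), refit,
#' and retained at `p_final` (default 0.1).
#'
#' @param delta_table Data frame from [delta_features()] (or any
#'   subjects x features table; `subject_id` column ignored). `NA` cells
#'   are median-imputed for the multivariate stages (count logged).
#' @param outcomes Data frame with `time` and `event` (>= 10 events).
#' @inheritParams select_clinical
#' @param vif_max VIF elimination threshold.
#' @param top_k Number of features kept by coefficient magnitude.
#' @param p_final Retention threshold for the final refit.
#' @return A `selection_result`.
#' @export
select_radiomic <- function(delta_table, outcomes, p_stage1 = 0.05,
                            vif_max = 5, top_k = 5L, p_final = 0.1) {
  if (sum(outcomes$event) < 10L) stop("need at least 10 events")
  x <- as.matrix(delta_table[, setdiff(names(delta_table), "subject_id"),
                             drop = FALSE])
  storage.mode(x) <- "double"
  n_na <- sum(is.na(x))
  # median-impute residual NA cells, drop degenerate columns
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- stats::median(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2, stats::sd)
  x <- x[, is.finite(sds) & sds > 0, drop = FALSE]
  x <- scale(x)
  log_ <- stage_entry("screen_input",
                      sprintf("nonconstant features (%d NA cells imputed)", n_na),
                      ncol(delta_table) - 1L, ncol(x))

  uni <- cox_univariate(x, outcomes$time, outcomes$event)
  keep1 <- uni$feature[!is.na(uni$p) & uni$p < p_stage1]
  log_ <- rbind(log_, stage_entry("univariate", paste0("p<", p_stage1),
                                  ncol(x), length(keep1)))
  empty <- structure(list(stage_log = log_, final_features = character(0),
                          coefficients = numeric(0)),
                     class = "selection_result")
  if (length(keep1) == 0L) return(empty)

  keep2 <- if (length(keep1) >= 2L)
    prune_vif(x[, keep1, drop = FALSE], vif_max) else keep1
  log_ <- rbind(log_, stage_entry("vif", paste0("VIF<=", vif_max),
                                  length(keep1), length(keep2)))

  # guard the multivariate fit against p approaching the event count
  max_mv <- max(2L, floor(sum(outcomes$event) / 2))
  if (length(keep2) > max_mv) {
    ord <- order(uni$p[match(keep2, uni$feature)])
    keep2 <- keep2[ord][seq_len(max_mv)]
    log_ <- rbind(log_, stage_entry("cap", paste0("best ", max_mv,
                                                  " by univariate p"),
                                    length(ord), max_mv))
  }

  df <- data.frame(x[, keep2, drop = FALSE], check.names = FALSE)
  fit <- tryCatch(
    survival::coxph(survival::Surv(outcomes$time, outcomes$event) ~ .,
                    data = df, ties = "efron"),
    error = function(e) NULL)
  if (is.null(fit)) return(empty)
  beta <- stats::coef(fit)
  names(beta) <- keep2
  beta <- beta[is.finite(beta)]
  ord <- order(-abs(beta), names(beta))     # lexicographic tie-break
  topn <- names(beta)[ord][seq_len(min(top_k, length(beta)))]
  if (length(beta) < top_k)
    log_ <- rbind(log_, stage_entry("rank", "fewer survivors than top_k; kept all",
                                    length(keep2), length(topn)))
  else
    log_ <- rbind(log_, stage_entry("rank", paste0("top ", top_k,
                                                   " |standardized coef|"),
                                    length(keep2), length(topn)))

  refit <- survival::coxph(
    survival::Surv(outcomes$time, outcomes$event) ~ .,
    data = data.frame(x[, topn, drop = FALSE], check.names = FALSE),
    ties = "efron")
  sref <- summary(refit)$coefficients
  pvals <- sref[, "Pr(>|z|)"]
  final <- topn[pvals < p_final]
  if (length(final) == 0L) {
    final <- topn[which.max(abs(sref[, "coef"]))]
    log_ <- rbind(log_, stage_entry("final", "none below p threshold; kept top coefficient",
                                    length(topn), 1L))
  } else {
    log_ <- rbind(log_, stage_entry("final", paste0("p<", p_final),
                                    length(topn), length(final)))
  }
  coefs <- stats::coef(refit)[match(final, topn)]
  names(coefs) <- final
  structure(list(stage_log = log_, final_features = final,
                 coefficients = coefs),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$final_features), " feature(s): ",
      paste(x$final_features, collapse = ", "), "\n", sep = "")
  print(x$stage_log, row.names = FALSE)
  invisible(x)
}

#' Restrict a feature matrix to k features by a selector's criterion
#'
#' * `kbest`: largest univariate Cox partial-likelihood score statistics;
#' * `lasso` / `elasticnet`: penalized Cox path (alpha 1 / 0.5), taking the
#'   first lambda with at least k nonzero coefficients and the k largest
#'   magnitudes there;
#' * `ridge`: alpha-0 penalized Cox at the smallest path lambda, k largest
#'   standardized coefficient magnitudes.
#'
#' @param x Numeric feature matrix (subjects x features).
#' @param outcomes Data frame with `time`, `event`.
#' @param selector One of `"kbest"`, `"lasso"`, `"ridge"`, `"elasticnet"`.
#' @param k Number of features to keep (default 5).
#' @return Character vector of selected feature names.
#' @export
select_k_features <- function(x, outcomes,
                              selector = c("kbest", "lasso", "ridge",
                                           "elasticnet"),
                              k = 5L) {
  selector <- match.arg(selector)
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  k <- min(k, ncol(x))
  y <- survival::Surv(outcomes$time, outcomes$event)
  if (selector == "kbest") {
    sc <- vapply(colnames(x), function(f) {
      fit <- tryCatch(survival::coxph(y ~ x[, f], ties = "efron"),
                      error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) return(-Inf)
      unname(fit$score)
    }, numeric(1))
    return(colnames(x)[order(-sc, colnames(x))][seq_len(k)])
  }
  alpha <- switch(selector, lasso = 1, elasticnet = 0.5, ridge = 0)
  fit <- glmnet::glmnet(scale(x), y, family = "cox", alpha = alpha,
                        nlambda = 50)
  b <- as.matrix(fit$beta)
  if (selector == "ridge") {
    co <- b[, ncol(b)]
  } else {
    nnz <- colSums(b != 0)
    idx <- which(nnz >= k)[1]
    if (is.na(idx)) idx <- ncol(b)
    co <- b[, idx]
  }
  names(co)[order(-abs(co), names(co))][seq_len(k)]
}

#' Benchmark feature selectors against survival learners
#'
#' For every (selector, learner) pair, restricts the features to
#' `k_features` by the selector's criterion and evaluates the learner by
#' IPCW time-dependent AUC at `horizon_days` under k-fold cross-validation
#' repeated `repeats` times (selection and fitting happen inside the
#' training folds only).
#'
#' @param delta_table Subjects x features data frame (`subject_id` ignored).
#' @param outcomes Data frame with `time`, `event`.
#' @param selectors,learners Method names; defaults give the 4 x 5 grid.
#' @param k_features Features per model (default 5).
#' @param k,repeats Cross-validation scheme (default 5-fold x 10).
#' @param horizon_days Evaluation horizon (default 383, the median PFS).
#' @param seed Integer seed.
#' @return List with `grid` (data frame: selector, learner, mean_auc,
#'   sd_auc, n_folds, n_failed), `best` (argmax row), and `flagged`
#'   (pairs with > 20% failed folds).
#' @export
benchmark_selectors <- function(delta_table, outcomes,
                                selectors = c("kbest", "lasso", "ridge",
                                              "elasticnet"),
                                learners = survival_learner_names(),
                                k_features = 5L, k = 5L, repeats = 10L,
                                horizon_days = 383, seed = 1L) {
  x <- as.matrix(delta_table[, setdiff(names(delta_table), "subject_id"),
                             drop = FALSE])
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- stats::median(x[, j], na.rm = TRUE)
  }
  folds <- make_cv_folds(outcomes$event, k, repeats,
                         stage_seed(seed, "benchmark"))
  rows <- list()
  for (sel in selectors) for (lrn in learners) {
    aucs <- numeric(0); failed <- 0L
    for (fd in folds) {
      res <- tryCatch({
        feats <- select_k_features(x[fd$train, , drop = FALSE],
                                   outcomes[fd$train, ], sel, k_features)
        lr <- survival_learner(lrn)
        mod <- lr$fit(x[fd$train, feats, drop = FALSE],
                      outcomes$time[fd$train], outcomes$event[fd$train],
                      seed = seed)
        risk <- lr$predict(mod, x[fd$test, feats, drop = FALSE])
        time_dependent_auc(risk, outcomes$time[fd$test],
                           outcomes$event[fd$test], horizon_days)
      }, error = function(e) NA_real_)
      if (is.na(res)) failed <- failed + 1L else aucs <- c(aucs, res)
    }
    rows[[paste(sel, lrn)]] <- data.frame(
      selector = sel, learner = lrn,
      mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
      n_folds = length(aucs), n_failed = failed,
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  flagged <- grid[grid$n_failed > 0.2 * length(folds), c("selector", "learner")]
  list(grid = grid, best = grid[which.max(grid$mean_auc), ],
       flagged = flagged)
}
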