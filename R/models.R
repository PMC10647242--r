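# Risk models: Cox proportional hazards (the primary model), alternative
# survival learners behind a common interface, holdout splitting and
# repeated cross-validation.

#' Fit a Cox proportional-hazards risk model
#'
#' Features are standardized inside the fit (parameters stored for
#' test-time reuse); the partial likelihood is maximized with the Efron
#' tie correction. The summary table reports, per coefficient, the SE,
#' Wald p-value, hazard ratio and its 95% CI.
#'
#' @param x Numeric matrix/data frame of features (n > number of features).
#' @param outcomes Data frame with `time` (> 0) and `event` (0/1, >= 1
#'   event).
#' @param standardize Center/scale features before fitting (default TRUE).
#' @return A `risk_model` with elements `kind`, `coefficients`, `summary`
#'   (coef, se, p, HR, CI bounds), `features`, `center`, `scale`.
#' @export
fit_coxph <- function(x, outcomes, standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) > ncol(x), sum(outcomes$event) >= 1L,
            all(outcomes$time > 0))
  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  df <- data.frame(xs, check.names = FALSE)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(outcomes$time, outcomes$event) ~ .,
                    data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w)))
        stop("convergence error in Cox fit: ", conditionMessage(w),
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)$coefficients
  ci <- summary(fit)$conf.int
  tab <- data.frame(
    feature = colnames(x),
    coef = s[, "coef"], se = s[, "se(coef)"], p = s[, "Pr(>|z|)"],
    hr = exp(s[, "coef"]),
    hr_lower = ci[, "lower .95"], hr_upper = ci[, "upper .95"],
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(
    kind = "coxph", coefficients = stats::setNames(s[, "coef"], colnames(x)),
    summary = tab, features = colnames(x), center = ctr, scale = scl
  ), class = "risk_model")
}

#' Predict risk scores from a fitted risk model
#'
#' Higher scores mean earlier expected progression.
#'
#' @param object A `risk_model`.
#' @param newdata Matrix/data frame containing the training features.
#' @param ... Unused.
#' @return Numeric risk vector.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  drop(xs %*% object$coefficients)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model:", x$kind, "> ", length(x$features), " feature(s)\n",
      sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

## ---- learner interface -----------------------------------------------------

#' Names of the available survival learners
#' @export
survival_learner_names <- function() {
  c("coxph", "survival_tree", "random_survival_forest", "fast_svm",
    "gradient_boosting")
}

# linear survival ranking SVM: squared hinge on comparable pairs with L2
# penalty, solved by iterating the active set of violated pairs
fit_svm_rank <- function(x, time, event, cost = 1, max_pairs = 2000L,
                         seed = 1L) {
  x <- as.matrix(x)
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  idx <- which(outer(time, time, "<") & event == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no comparable pairs for ranking SVM")
  if (nrow(idx) > max_pairs) {
    sel <- with_local_seed(seed, sample.int(nrow(idx), max_pairs))
    idx <- idx[sel, , drop = FALSE]
  }
  d <- xs[idx[, 1], , drop = FALSE] - xs[idx[, 2], , drop = FALSE]
  p <- ncol(xs)
  w <- rep(0, p)
  for (it in 1:50) {
    margin <- drop(d %*% w)
    act <- margin < 1
    if (!any(act)) break
    da <- d[act, , drop = FALSE]
    a <- diag(p) + cost * crossprod(da)
    w_new <- drop(solve(a, cost * colSums(da)))
    if (max(abs(w_new - w)) < 1e-8) { w <- w_new; break }
    w <- w_new
  }
  list(w = w, center = ctr, scale = scl)
}

#' A survival learner behind a uniform fit/predict interface
#'
#' Learners: `coxph` (proportional hazards), `survival_tree` (recursive
#' partitioning with exponential splitting), `random_survival_forest`
#' (ranger; risk = total cumulative hazard), `fast_svm` (linear survival
#' ranking SVM with squared hinge loss), `gradient_boosting` (boosted Cox
#' trees via xgboost). All return a real-valued risk, higher = earlier
#' progression.
#'
#' @param name One of [survival_learner_names()].
#' @return List with functions `fit(x, time, event, seed)` and
#'   `predict(model, x)`.
#' @export
survival_learner <- function(name = survival_learner_names()) {
  name <- match.arg(name)
  switch(name,
    coxph = list(
      fit = function(x, time, event, seed = 1L)
        fit_coxph(x, data.frame(time = time, event = event)),
      predict = function(model, x) predict.risk_model(model, x)
    ),
    survival_tree = list(
      fit = function(x, time, event, seed = 1L) {
        df <- data.frame(x, check.names = FALSE)
        df$.surv <- survival::Surv(time, event)
        rpart::rpart(.surv ~ ., data = df,
                     control = rpart::rpart.control(
                       minsplit = 10, cp = 0.01, xval = 0))
      },
      predict = function(model, x)
        stats::predict(model, newdata = data.frame(x, check.names = FALSE))
    ),
    random_survival_forest = list(
      fit = function(x, time, event, seed = 1L) {
        df <- data.frame(time = time, event = event, x, check.names = FALSE)
        ranger::ranger(survival::Surv(time, event) ~ ., data = df,
                       num.trees = 200, num.threads = 1, seed = seed)
      },
      predict = function(model, x) {
        pr <- stats::predict(model, data = data.frame(x, check.names = FALSE),
                             num.threads = 1)
        rowSums(pr$chf)
      }
    ),
    fast_svm = list(
      fit = function(x, time, event, seed = 1L)
        fit_svm_rank(x, time, event, seed = seed),
      predict = function(model, x) {
        xs <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
        drop(xs %*% model$w)
      }
    ),
    gradient_boosting = list(
      fit = function(x, time, event, seed = 1L) {
        label <- ifelse(event == 1, time, -time)
        dm <- xgboost::xgb.DMatrix(as.matrix(x), label = label)
        xgboost::xgb.train(
          params = list(objective = "survival:cox", eta = 0.1, max_depth = 2,
                        nthread = 1, seed = seed),
          data = dm, nrounds = 100, verbose = 0)
      },
      predict = function(model, x)
        log(stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x))))
    )
  )
}

## ---- splitting and cross-validation ----------------------------------------

#' Event-stratified holdout split
#'
#' Splits subjects into disjoint, exhaustive train/test sets, sampling
#' events and censored subjects separately so the event fraction is
#' preserved; falls back to a plain random split (with a warning) when
#' there are fewer than 2 events or 2 censored subjects.
#'
#' @param outcomes Data frame with `event`.
#' @param fraction Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_holdout <- function(outcomes, fraction = 0.7, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(outcomes)
  ev <- which(outcomes$event == 1)
  ce <- which(outcomes$event == 0)
  with_local_seed(seed, {
    if (length(ev) < 2L || length(ce) < 2L) {
      warning("too few events to stratify; plain random split")
      train <- sort(sample.int(n, round(fraction * n)))
    } else {
      train <- sort(c(sample(ev, round(fraction * length(ev))),
                      sample(ce, round(fraction * length(ce)))))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

# event-stratified fold assignments for k-fold CV repeated `repeats` times
make_cv_folds <- function(event, k = 5L, repeats = 10L, seed = 1L) {
  n <- length(event)
  with_local_seed(seed, {
    folds <- list()
    for (r in seq_len(repeats)) {
      assign_grp <- integer(n)
      for (g in unique(event)) {
        ix <- which(event == g)
        assign_grp[ix] <- sample(rep_len(seq_len(k), length(ix)))
      }
      for (f in seq_len(k)) {
        folds[[length(folds) + 1L]] <- list(
          repeat_ = r, fold = f,
          train = which(assign_grp != f), test = which(assign_grp == f))
      }
    }
    folds
  })
}

#' Repeated k-fold cross-validation of a survival learner
#'
#' Folds are event-stratified; any feature selection must happen inside
#' the training folds, which is what the optional `selector` argument
#' does. A fold whose test part has no events is reshuffled once; if the
#' problem persists, an error is raised.
#'
#' @param x Feature matrix.
#' @param outcomes Data frame with `time`, `event`.
#' @param learner Learner name (see [survival_learner_names()]).
#' @param k Folds (>= 2), default 5.
#' @param repeats Repetitions, default 10.
#' @param seed Integer seed.
#' @param horizon_days Horizon for the fold AUC (default 383).
#' @param selector Optional selector name passed to [select_k_features()],
#'   applied within each training fold.
#' @param k_features Features kept by the selector.
#' @return Data frame with one row per fold: `repeat_`, `fold`, `cindex`,
#'   `auc`.
#' @export
cross_validate <- function(x, outcomes, learner = "coxph", k = 5L,
                           repeats = 10L, seed = 1L, horizon_days = 383,
                           selector = NULL, k_features = 5L) {
  stopifnot(k >= 2L)
  x <- as.matrix(x)
  folds <- make_cv_folds(outcomes$event, k, repeats, stage_seed(seed, "cv"))
  if (any(vapply(folds, function(f) sum(outcomes$event[f$test]) == 0, TRUE))) {
    folds <- make_cv_folds(outcomes$event, k, repeats,
                           stage_seed(seed, "cv") + 1L)
    if (any(vapply(folds, function(f) sum(outcomes$event[f$test]) == 0, TRUE)))
      stop("empty-event fold after reshuffle")
  }
  lr <- survival_learner(learner)
  rows <- lapply(folds, function(fd) {
    feats <- colnames(x)
    if (!is.null(selector))
      feats <- select_k_features(x[fd$train, , drop = FALSE],
                                 outcomes[fd$train, ], selector, k_features)
    mod <- lr$fit(x[fd$train, feats, drop = FALSE], outcomes$time[fd$train],
                  outcomes$event[fd$train], seed = seed)
    risk <- lr$predict(mod, x[fd$test, feats, drop = FALSE])
    auc <- tryCatch(
      time_dependent_auc(risk, outcomes$time[fd$test],
                         outcomes$event[fd$test], horizon_days),
      error = function(e) NA_real_)
    data.frame(repeat_ = fd$repeat_, fold = fd$fold,
               cindex = concordance_index(risk, outcomes$time[fd$test],
                                          outcomes$event[fd$test]),
               auc = auc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
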