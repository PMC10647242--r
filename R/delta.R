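# Test-retest reliability filtering (ICC(2,1)) and the delta-radiomics
# transforms: percentage change, time-adjusted percentage change, and
# time-adjusted log ratio of follow-up over pre-treatment features.

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' ANOVA mean squares of an n-subject x k-rater table.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns.
#' @return The ICC estimate (`NA` if the subject variance is degenerate).
#' @export
icc21 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 3L, k >= 2L)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  (msr - mse) / denom
}

#' Filter features by test-retest ICC
#'
#' Computes ICC(2,1) per feature across two repeated measurements (e.g. two
#' readers' segmentations) and retains features whose ICC exceeds the
#' threshold. Features with zero variance across subjects in either
#' measurement are dropped with a warning (their ICC is undefined).
#'
#' @param rater1,rater2 Numeric matrices or data frames with identical
#'   subjects (rows) and feature names (columns); at least 3 subjects.
#' @param threshold ICC retention threshold, default 0.80.
#' @return Character vector of retained feature names, with the per-feature
#'   ICC values attached as `attr(, "icc")`.
#' @export
icc_filter <- function(rater1, rater2, threshold = 0.80) {
  r1 <- as.matrix(rater1); r2 <- as.matrix(rater2)
  if (!identical(dim(r1), dim(r2)) ||
      !identical(colnames(r1), colnames(r2)))
    stop("retest pair must share subjects and feature names")
  if (nrow(r1) < 3L) stop("ICC needs at least 3 retest subjects")
  feats <- colnames(r1)
  icc <- vapply(feats, function(f) {
    x <- cbind(r1[, f], r2[, f])
    if (stats::sd(x[, 1]) == 0 && stats::sd(x[, 2]) == 0) return(NA_real_)
    icc21(x)
  }, numeric(1))
  n_undef <- sum(is.na(icc))
  if (n_undef > 0)
    warning(n_undef, " zero-variance feature(s) dropped (ICC undefined)")
  keep <- feats[!is.na(icc) & icc > threshold]
  attr(keep, "icc") <- icc
  keep
}

#' Build a feature table from per-subject feature vectors
#'
#' @param pre,post Matrices/data frames of features (subjects x features)
#'   for the pre-treatment and follow-up scans, same subjects and columns.
#' @param subject_id Subject identifiers.
#' @param interval_days Positive inter-scan interval per subject.
#' @return A `feature_table` data frame in long-by-timepoint layout.
#' @export
feature_table <- function(pre, post, subject_id, interval_days) {
  pre <- as.data.frame(pre); post <- as.data.frame(post)
  stopifnot(nrow(pre) == nrow(post),
            identical(names(pre), names(post)),
            length(subject_id) == nrow(pre),
            length(interval_days) == nrow(pre))
  if (any(interval_days <= 0)) stop("interval_days must be > 0")
  out <- rbind(
    cbind(subject_id = subject_id, timepoint = "pretreat",
          interval_days = interval_days, pre, stringsAsFactors = FALSE),
    cbind(subject_id = subject_id, timepoint = "follow",
          interval_days = interval_days, post, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Delta-method labels in canonical order
#' @export
delta_methods <- function() {
  c("pretreat_only", "follow_only", "delta", "delta_time", "delta_log_time")
}

#' Compute delta-radiomics transforms
#'
#' For pre-treatment value p, follow-up value f and inter-scan interval
#' `dt` (days):
#' * `delta`: `(f - p) / p` (percentage change),
#' * `delta_time`: `(1 / dt) * (f - p) / p`,
#' * `delta_log_time`: `(1 / dt) * (log f - log p)`,
#' * `pretreat_only` / `follow_only`: the raw values at one timepoint.
#'
#' Cells where the transform is undefined (p = 0 for the ratio forms,
#' non-positive values for the log form) become `NA`; their count is
#' reported in `attr(, "n_invalid")` rather than aborting.
#'
#' @param table A [feature_table()] with both timepoints per subject.
#' @param method One of [delta_methods()].
#' @return Data frame `subject_id` + one column per feature, with
#'   attributes `method`, `interval_days`, `n_invalid`.
#' @export
delta_features <- function(table, method = delta_methods()) {
  method <- match.arg(method)
  stopifnot(inherits(table, "data.frame"))
  feats <- setdiff(names(table), c("subject_id", "timepoint", "interval_days"))
  pre <- table[table$timepoint == "pretreat", , drop = FALSE]
  post <- table[table$timepoint == "follow", , drop = FALSE]
  if (!setequal(pre$subject_id, post$subject_id) || nrow(pre) == 0L)
    stop("both timepoints must be present for every subject")
  post <- post[match(pre$subject_id, post$subject_id), , drop = FALSE]
  p <- as.matrix(pre[, feats, drop = FALSE])
  f <- as.matrix(post[, feats, drop = FALSE])
  dt <- pre$interval_days
  vals <- switch(method,
    pretreat_only = p,
    follow_only = f,
    delta = {
      bad <- p == 0
      v <- (f - p) / p; v[bad] <- NA; v
    },
    delta_time = {
      bad <- p == 0
      v <- (f - p) / p / dt; v[bad] <- NA; v
    },
    delta_log_time = {
      bad <- p <= 0 | f <= 0
      v <- suppressWarnings((log(f) - log(p)) / dt); v[bad] <- NA; v
    }
  )
  n_invalid <- sum(is.na(vals))
  out <- data.frame(subject_id = pre$subject_id, vals,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "interval_days") <- dt
  attr(out, "n_invalid") <- n_invalid
  out
}
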