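# Evaluation: Harrell's C-index, IPCW time-dependent ROC/AUC at fixed
# horizons, bootstrap model comparison with paired t-tests, Youden-index
# risk thresholding, Kaplan-Meier stratification with log-rank testing and
# Schoenfeld power.

DAYS_PER_MONTH <- 30.44

#' Default evaluation horizons (6, 9, 12, 15 months) in days
#' @export
default_horizons_days <- function() round(c(6, 9, 12, 15) * DAYS_PER_MONTH)

#' Harrell's concordance index
#'
#' Fraction of usable (comparable) subject pairs in which the
#' higher-risk subject progresses earlier; ties in risk count 1/2.
#'
#' @param risk Numeric risk scores (higher = earlier progression).
#' @param time Survival times.
#' @param event Event indicators (1 = progression, 0 = censored).
#' @return The C-index in [0, 1].
#' @export
concordance_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  if (length(time) < 2L || sum(event) == 0L)
    stop("undefined metric: no comparable pairs")
  cf <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("undefined metric: no comparable pairs")
  unname(cf$concordance)
}

# Kaplan-Meier estimate of the censoring distribution G(t), evaluated
# just before t when `before` is TRUE
censoring_survival <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t, before = FALSE) {
    tt <- if (before) t - 1e-9 else t
    s <- summary(fit, times = pmin(tt, max(fit$time)), extend = TRUE)$surv
    pmax(s, 1e-12)
  }
}

#' IPCW time-dependent (cumulative/dynamic) AUC at a horizon
#'
#' Discrimination between subjects who progress by the horizon (cases:
#' observed events with time <= horizon) and those still event-free past
#' it (controls: time > horizon), with inverse-probability-of-censoring
#' weights from the Kaplan-Meier censoring distribution. With no
#' censoring this reduces to the plain (Mann-Whitney) AUC of
#' event-by-horizon status against risk.
#'
#' @inheritParams concordance_index
#' @param horizon_days Evaluation horizon (days).
#' @return The AUC estimate in [0, 1].
#' @export
time_dependent_auc <- function(risk, time, event, horizon_days) {
  cases <- which(time <= horizon_days & event == 1)
  controls <- which(time > horizon_days)
  if (length(cases) == 0L || length(controls) == 0L)
    stop("undefined metric: no cases or no controls at horizon")
  g <- censoring_survival(time, event)
  w_case <- 1 / g(time[cases], before = TRUE)
  w_ctrl <- rep(1 / g(horizon_days), length(controls))
  rc <- risk[cases]; rk <- risk[controls]
  # weighted Mann-Whitney via the rank trick: for each case, total control
  # weight with smaller risk (+ half of ties)
  ord <- order(rk)
  rk_s <- rk[ord]; w_s <- w_ctrl[ord]
  cw <- cumsum(w_s)
  lt <- findInterval(rc, rk_s, left.open = TRUE)    # controls strictly below
  le <- findInterval(rc, rk_s)                      # controls <= case risk
  cw0 <- c(0, cw)
  below <- cw0[lt + 1L]
  ties <- cw0[le + 1L] - below
  num <- sum(w_case * (below + 0.5 * ties))
  num / (sum(w_case) * sum(w_ctrl))
}

#' Bootstrap comparison of two risk models
#'
#' Resamples subjects with replacement `B` times, computes both models'
#' time-dependent AUC at each horizon (and C-index) per replicate, and
#' compares the paired replicate metrics with a two-sided paired t-test.
#' Degenerate replicates (no events, or undefined AUC at every horizon)
#' are redrawn, up to `10 * B` attempts, so B stays fixed.
#'
#' @param risk_a,risk_b Risk vectors of the two models on the same subjects.
#' @inheritParams concordance_index
#' @param horizons_days Horizons at which to compare (days).
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return List with `p_values` (per horizon), `p_cindex`, `replicates`
#'   (per-replicate metric data frame) and `n_redrawn`.
#' @export
bootstrap_compare <- function(risk_a, risk_b, time, event,
                              horizons_days = default_horizons_days(),
                              B = 100L, seed = 1L) {
  stopifnot(B >= 2L)
  n <- length(time)
  reps <- vector("list", B)
  n_redrawn <- 0L
  with_local_seed(stage_seed(seed, "bootstrap"), {
    b <- 1L; attempts <- 0L
    while (b <= B && attempts < 10L * B) {
      attempts <- attempts + 1L
      ix <- sample.int(n, n, replace = TRUE)
      if (sum(event[ix]) == 0L) { n_redrawn <- n_redrawn + 1L; next }
      row <- list(replicate = b)
      ok <- FALSE
      for (h in horizons_days) {
        aa <- tryCatch(time_dependent_auc(risk_a[ix], time[ix], event[ix], h),
                       error = function(e) NA_real_)
        bb <- tryCatch(time_dependent_auc(risk_b[ix], time[ix], event[ix], h),
                       error = function(e) NA_real_)
        row[[paste0("auc_a_", h)]] <- aa
        row[[paste0("auc_b_", h)]] <- bb
        if (!is.na(aa) && !is.na(bb)) ok <- TRUE
      }
      if (!ok) { n_redrawn <- n_redrawn + 1L; next }
      row$cindex_a <- tryCatch(
        concordance_index(risk_a[ix], time[ix], event[ix]),
        error = function(e) NA_real_)
      row$cindex_b <- tryCatch(
        concordance_index(risk_b[ix], time[ix], event[ix]),
        error = function(e) NA_real_)
      reps[[b]] <- as.data.frame(row)
      b <- b + 1L
    }
  })
  reps <- do.call(rbind, reps)
  paired_p <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2L) return(NA_real_)
    d <- a[ok] - b[ok]
    if (stats::sd(d) == 0) return(1)
    stats::t.test(d)$p.value
  }
  p_values <- vapply(horizons_days, function(h)
    paired_p(reps[[paste0("auc_a_", h)]], reps[[paste0("auc_b_", h)]]),
    numeric(1))
  names(p_values) <- paste0(horizons_days, "d")
  list(p_values = p_values,
       p_cindex = paired_p(reps$cindex_a, reps$cindex_b),
       replicates = reps, n_redrawn = n_redrawn)
}

# IPCW sensitivity/specificity pairs over candidate thresholds
ipcw_roc_points <- function(risk, time, event, horizon_days) {
  cases <- which(time <= horizon_days & event == 1)
  controls <- which(time > horizon_days)
  if (length(cases) == 0L || length(controls) == 0L)
    stop("undefined ROC: no cases or no controls at horizon")
  g <- censoring_survival(time, event)
  w_case <- 1 / g(time[cases], before = TRUE)
  thr <- sort(unique(risk))
  sens <- vapply(thr, function(cc)
    sum(w_case * (risk[cases] > cc)) / sum(w_case), numeric(1))
  spec <- vapply(thr, function(cc)
    mean(risk[controls] <= cc), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Youden-index classification threshold
#'
#' Maximizes J = sensitivity + specificity - 1 on the IPCW ROC of the
#' training risks at the given horizon (subjects with risk above the
#' threshold are called high-risk). Ties in J resolve to the lower
#' threshold.
#'
#' @inheritParams concordance_index
#' @param horizon_days ROC horizon (days); default 383, the median PFS.
#' @return The threshold, with the achieved J as `attr(, "youden")`.
#' @export
youden_threshold <- function(risk, time, event, horizon_days = 383) {
  roc <- ipcw_roc_points(risk, time, event, horizon_days)
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)[1]   # lower threshold wins ties
  structure(roc$threshold[best], youden = j[best])
}

#' Two-sided Schoenfeld power of the log-rank test
#'
#' `power = Phi(-z + sqrt(d p (1-p)) |log HR|) + Phi(-z - sqrt(...))`
#' with `z` the upper alpha/2 normal quantile, `d` the total number of
#' events and `p` the allocation fraction of one group; at HR = 1 the
#' power equals alpha.
#'
#' @param hazard_ratio Assumed hazard ratio between the groups.
#' @param n_events Total observed events.
#' @param allocation Fraction of subjects in the first group.
#' @param alpha Two-sided significance level (default 0.05).
#' @return The power in [0, 1].
#' @export
schoenfeld_power <- function(hazard_ratio, n_events, allocation = 0.5,
                             alpha = 0.05) {
  stopifnot(hazard_ratio > 0, n_events >= 0,
            allocation > 0, allocation < 1)
  z <- stats::qnorm(1 - alpha / 2)
  eff <- sqrt(n_events * allocation * (1 - allocation)) *
    abs(log(hazard_ratio))
  stats::pnorm(-z + eff) + stats::pnorm(-z - eff)
}

#' Kaplan-Meier stratification with log-rank test and power
#'
#' Product-limit survival estimates per group with Greenwood-based 95%
#' bands, the two-group log-rank chi-square statistic and p-value, the
#' between-group hazard ratio (from a one-covariate Cox fit) and the
#' Schoenfeld power of the log-rank test at alpha = 0.05. With no events
#' the log-rank test is undefined and flagged (`logrank_defined = FALSE`).
#'
#' @param group Factor/character vector with exactly two nonempty levels
#'   (e.g. `"high"` / `"low"`).
#' @inheritParams concordance_index
#' @return List: `km_curves` (data frame of step functions with bands),
#'   `logrank_stat`, `logrank_p`, `logrank_defined`, `hazard_ratio`,
#'   `power`, `group_sizes`.
#' @export
km_logrank <- function(group, time, event) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L || any(table(group) == 0L))
    stop("grouping error: exactly two nonempty groups required")
  sf <- survival::survfit(survival::Surv(time, event) ~ group,
                          conf.type = "log")
  km <- data.frame(
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    surv = sf$surv, lower = sf$lower, upper = sf$upper,
    stringsAsFactors = FALSE)
  if (sum(event) == 0L) {
    return(list(km_curves = km, logrank_stat = NA_real_,
                logrank_p = NA_real_, logrank_defined = FALSE,
                hazard_ratio = NA_real_, power = NA_real_,
                group_sizes = table(group)))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd_$chisq
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  cx <- tryCatch(
    suppressWarnings(
      exp(stats::coef(survival::coxph(survival::Surv(time, event) ~ group)))),
    error = function(e) NA_real_)
  pw <- if (is.na(cx)) NA_real_ else
    schoenfeld_power(cx, sum(event), mean(group == levels(group)[1]))
  list(km_curves = km, logrank_stat = unname(stat), logrank_p = unname(p),
       logrank_defined = TRUE, hazard_ratio = unname(cx),
       power = unname(pw), group_sizes = table(group))
}

#' Evaluate a risk vector against outcomes
#'
#' Bundles the C-index and the IPCW AUC at each horizon into one report
#' row; undefined horizons yield `NA`.
#'
#' @inheritParams concordance_index
#' @param horizons_days Horizons in days.
#' @return Named list: `c_index`, `auc` (named by horizon).
#' @export
evaluate_risk <- function(risk, time, event,
                          horizons_days = default_horizons_days()) {
  auc <- vapply(horizons_days, function(h)
    tryCatch(time_dependent_auc(risk, time, event, h),
             error = function(e) NA_real_), numeric(1))
  names(auc) <- paste0(horizons_days, "d")
  list(c_index = tryCatch(concordance_index(risk, time, event),
                          error = function(e) NA_real_),
       auc = auc)
}
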