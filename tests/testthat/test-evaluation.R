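# C-index, time-dependent AUC, bootstrap comparison, Youden thresholding,
# Kaplan-Meier / log-rank and Schoenfeld power.

test_that("perfect and inverted rankings give C-index 1 and 0", {
  time <- c(5, 3, 9, 1, 7)
  event <- rep(1, 5)
  expect_equal(concordance_index(-time, time, event), 1)
  expect_equal(concordance_index(time, time, event), 0)
})

test_that("C-index equals exhaustive pair enumeration on a censored 20-subject toy", {
  set.seed(2)
  n <- 20
  time <- sample(1:40, n)
  event <- rbinom(n, 1, 0.6)
  risk <- rnorm(n)
  num <- den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (time[i] < time[j] && event[i] == 1) {     # i progresses first
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  expect_equal(concordance_index(risk, time, event), num / den,
               tolerance = 1e-12)
  expect_error(concordance_index(1, 5, 0), "no comparable")
})

test_that("C-index of r and -r sum to one without ties", {
  set.seed(3)
  oc <- draw_surv(rnorm(30), seed = 4)
  r <- rnorm(30)
  expect_equal(concordance_index(r, oc$time, oc$event) +
                 concordance_index(-r, oc$time, oc$event), 1,
               tolerance = 1e-12)
})

test_that("C-index and AUC are invariant under monotone risk transforms", {
  set.seed(5)
  oc <- draw_surv(rnorm(60), seed = 6)
  r <- rnorm(60)
  expect_equal(concordance_index(r, oc$time, oc$event),
               concordance_index(exp(3 * r), oc$time, oc$event))
  expect_equal(time_dependent_auc(r, oc$time, oc$event, 383),
               time_dependent_auc(exp(3 * r), oc$time, oc$event, 383),
               tolerance = 1e-12)
})

test_that("with no censoring the horizon AUC reduces to the Mann-Whitney AUC", {
  set.seed(7)
  n <- 80
  time <- rexp(n, 1 / 400)
  event <- rep(1, n)
  risk <- -time + rnorm(n, sd = 100)
  h <- 383
  got <- time_dependent_auc(risk, time, event, h)
  lab <- as.integer(time <= h)
  w <- wilcox.test(risk[lab == 1], risk[lab == 0], exact = FALSE)
  oracle <- unname(w$statistic) / (sum(lab) * sum(1 - lab))
  expect_equal(got, oracle, tolerance = 1e-9)
  # perfectly separating risk
  expect_equal(time_dependent_auc(-time, time, event, h), 1)
})

test_that("random risks give horizon AUC near one half", {
  aucs <- sapply(1:20, function(s) {
    oc <- draw_surv(rep(0, 500), seed = s)
    set.seed(1000 + s)
    time_dependent_auc(rnorm(500), oc$time, oc$event, 383)
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("bootstrap comparison of a model with itself gives p near one", {
  oc <- draw_surv(rnorm(80), seed = 8)
  set.seed(9)
  r <- rnorm(80)
  bc <- bootstrap_compare(r, r, oc$time, oc$event, horizons_days = 383,
                          B = 30, seed = 1)
  expect_equal(unname(bc$p_values["383d"]), 1)
  # same seed reproduces replicate metrics exactly
  bc2 <- bootstrap_compare(r, r, oc$time, oc$event, horizons_days = 383,
                           B = 30, seed = 1)
  expect_identical(bc$replicates, bc2$replicates)
})

test_that("a strong model beats a null model with p below 0.001", {
  set.seed(10)
  n <- 300
  lp <- rnorm(n)
  oc <- draw_surv(2 * lp, seed = 11)
  set.seed(12)
  bc <- bootstrap_compare(rnorm(n), lp, oc$time, oc$event,
                          horizons_days = 383, B = 100, seed = 2)
  expect_lt(unname(bc$p_values["383d"]), 0.001)
})

test_that("Youden threshold separates groups and scans match an exhaustive oracle", {
  # perfectly separated risks
  time <- c(rep(100, 10), rep(900, 10))
  event <- rep(1, 20)
  risk <- c(rep(2, 10), rep(-2, 10))
  thr <- youden_threshold(risk, time, event, horizon_days = 383)
  expect_equal(attr(thr, "youden"), 1)
  expect_gte(thr, -2); expect_lt(thr, 2)

  # 10-point toy, uncensored: exhaustive threshold scan oracle
  set.seed(13)
  time2 <- sample(c(50, 800), 10, replace = TRUE)
  event2 <- rep(1, 10)
  risk2 <- rnorm(10)
  thr2 <- youden_threshold(risk2, time2, event2, horizon_days = 383)
  lab <- time2 <= 383
  cand <- sort(unique(risk2))
  j <- sapply(cand, function(cc)
    mean(risk2[lab] > cc) + mean(risk2[!lab] <= cc) - 1)
  expect_equal(as.numeric(thr2), cand[which.max(j)])
  expect_equal(attr(thr2, "youden"), max(j), tolerance = 1e-12)
})

test_that("null risks give a Youden index near zero", {
  js <- sapply(1:10, function(s) {
    oc <- draw_surv(rep(0, 300), seed = 40 + s)
    set.seed(60 + s)
    attr(youden_threshold(rnorm(300), oc$time, oc$event, 383), "youden")
  })
  expect_lt(mean(js), 0.15)
})

test_that("KM estimates, log-rank and duplicated-group behavior are exact", {
  time <- c(1, 2, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 0, 1)
  expect_error(km_logrank(rep("x", 6), time, event), "two nonempty groups")

  # hand-computed product-limit values for a mixed-censoring 6-subject arm:
  # deaths at t=1 (6 at risk), t=3 (3 at risk), t=5 (1 at risk)
  kl <- km_logrank(rep(c("g", "h"), c(3, 3)), time, event)
  g1 <- kl$km_curves[kl$km_curves$group == "g", ]   # times 1, 2, 2 -> t=1,2
  expect_equal(g1$surv[g1$time == 1], 1 - 1 / 3)

  # duplicated data in two groups: log-rank statistic 0
  time2 <- c(time, time); event2 <- c(event, event)
  grp2 <- rep(c("high", "low"), each = 6)
  kl <- km_logrank(grp2, time2, event2)
  expect_lt(kl$logrank_stat, 1e-9)
  expect_equal(kl$logrank_p, 1, tolerance = 1e-6)
  expect_true(all(kl$km_curves$surv <= 1))
  # survival starts at 1 and is non-increasing within each group
  for (g in c("high", "low")) {
    s <- kl$km_curves$surv[kl$km_curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("log-rank statistic matches the observed-minus-expected oracle", {
  set.seed(14)
  n <- 40
  grp <- rep(c("A", "B"), each = n / 2)
  lp <- ifelse(grp == "A", 0.8, -0.8)
  oc <- draw_surv(lp, seed = 15)
  kl <- km_logrank(grp, oc$time, oc$event)
  # oracle: standard log-rank from the 2xK risk tables
  tt <- sort(unique(oc$time[oc$event == 1]))
  o_a <- e_a <- v <- 0
  for (t in tt) {
    at <- oc$time >= t
    d <- sum(oc$time == t & oc$event == 1)
    d_a <- sum(oc$time == t & oc$event == 1 & grp == "A")
    n_r <- sum(at); n_a <- sum(at & grp == "A")
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n_r
    if (n_r > 1)
      v <- v + d * (n_a / n_r) * (1 - n_a / n_r) * (n_r - d) / (n_r - 1)
  }
  expect_equal(kl$logrank_stat, (o_a - e_a)^2 / v, tolerance = 1e-9)
})

test_that("no events flags the log-rank test as undefined", {
  kl <- km_logrank(rep(c("a", "b"), 5), time = 1:10, event = rep(0, 10))
  expect_false(kl$logrank_defined)
  expect_true(all(kl$km_curves$surv == 1))
})

test_that("Schoenfeld power equals alpha at HR 1 and is monotone", {
  expect_equal(schoenfeld_power(1, 100), 0.05)
  hrs <- c(1.2, 1.5, 2, 3)
  p_hr <- sapply(hrs, schoenfeld_power, n_events = 80)
  expect_true(all(diff(p_hr) > 0))
  ns <- c(20, 50, 100, 200)
  p_n <- sapply(ns, function(d) schoenfeld_power(1.8, d))
  expect_true(all(diff(p_n) > 0))
  # inverted HR gives the same power
  expect_equal(schoenfeld_power(0.5, 80), schoenfeld_power(2, 80))
})
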