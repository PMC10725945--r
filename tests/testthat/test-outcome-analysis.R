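# Risk grouping, survival statistics and cohort-characteristics tests.

test_that("assign_risk_groups: thresholds, labels, degenerate inputs", {
  g <- tiny_grid()
  roi_arr <- array(0L, g$shape); roi_arr[3:4, 3:4, 3:4] <- 1L
  roi <- structure(list(voxels = roi_arr, grid = g, label = "ROI2",
                        provenance = list()), class = "roi_mask")
  touching <- mask_from_indices(g, c(3, 3, 3), "touch")   # exactly 1 voxel
  apart <- mask_from_indices(g, c(1, 1, 1), "apart")

  ra <- assign_risk_groups(list(touching, apart), list(roi))
  expect_equal(ra$risk_group, c("high", "low"))
  expect_equal(ra$overlapping_rois, c("ROI2", ""))
  expect_equal(ra$overlap_ROI2, c(1, 0))
  expect_equal(ra$total_overlap_voxels, c(1, 0))

  expect_warning(ra0 <- assign_risk_groups(list(touching), list()), "low risk")
  expect_equal(ra0$risk_group, "low")
})

test_that("km_estimate matches the hand product-limit computation", {
  # 3 patients, deaths at 1, 2, 3: S = 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$curve$n_risk, c(3, 2, 1))

  # all censored: flat at 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$curve$survival == 1))

  # duplicating every record leaves the curve unchanged
  t <- c(1, 2, 2, 5, 7); e <- c(1, 0, 1, 1, 0)
  k1 <- km_estimate(t, e)
  k2 <- km_estimate(rep(t, 2), rep(e, 2))
  expect_equal(k2$curve$survival, k1$curve$survival)
  expect_equal(k2$curve$time, k1$curve$time)

  # monotone, bounded
  coh <- small_cohort(60, seed = 3)
  km3 <- km_estimate(coh$clinical$time, coh$clinical$event)
  expect_true(all(diff(km3$curve$survival) <= 1e-12))
  expect_true(all(km3$curve$survival >= 0 & km3$curve$survival <= 1))

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

# independent log-rank oracle: hypergeometric increments at each distinct
# event time (group A observed-minus-expected, variance summed)
oracle_logrank <- function(ta, ea, tb, eb) {
  times <- c(ta, tb); events <- c(ea, eb)
  grp_a <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n_a <- sum(at_risk & grp_a)
    d <- sum(events == 1 & times == t)
    d_a <- sum(events == 1 & times == t & grp_a)
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

test_that("logrank_test agrees with the hypergeometric-increment oracle", {
  set.seed(14)
  for (rep in 1:6) {
    ta <- round(rexp(25, 0.08), 3); ea <- rbinom(25, 1, 0.8)
    tb <- round(rexp(30, 0.15), 3); eb <- rbinom(30, 1, 0.8)
    got <- logrank_test(ta, ea, tb, eb)
    want <- oracle_logrank(ta, ea, tb, eb)
    expect_equal(got$chisq, want$chisq, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    # df = 1 identity: statistic is the squared standardized O - E sum
    expect_equal(sum(got$observed - got$expected), 0, tolerance = 1e-8)
    # label symmetry
    swapped <- logrank_test(tb, eb, ta, ea)
    expect_equal(swapped$chisq, got$chisq, tolerance = 1e-10)
  }
})

test_that("logrank_test contracts: identical groups, separation, no events", {
  t <- c(1, 3, 5, 7, 9); e <- c(1, 1, 0, 1, 1)
  same <- logrank_test(t, e, t, e)
  expect_lt(same$chisq, 1e-10); expect_gt(same$p, 0.999)

  sep <- logrank_test(rep(1, 20), rep(1, 20), rep(10, 20), rep(1, 20))
  expect_lt(sep$p, 0.001)

  expect_warning(z <- logrank_test(t, rep(0, 5), t + 1, rep(0, 5)),
                 "no events")
  expect_equal(z$p, 1)
})

test_that("cox_hazard_ratio: orientation, reciprocity, degenerate input", {
  set.seed(5)
  times <- c(rexp(80, 0.05), rexp(80, 0.10))
  events <- rep(1, 160)
  grp <- rep(c("low", "high"), each = 80)   # high has twice the hazard
  cx <- cox_hazard_ratio(times, events, grp, reference = "high")
  # low vs high: protective, HR < 1
  expect_lt(cx$hr, 1)
  expect_true(cx$ci[1] <= cx$hr && cx$hr <= cx$ci[2])
  rec <- cox_hazard_ratio(times, events, grp, reference = "low")
  expect_equal(rec$hr, 1 / cx$hr, tolerance = 1e-10)
  expect_equal(rec$hr, cx$hr_reciprocal, tolerance = 1e-10)

  expect_error(cox_hazard_ratio(times, events, rep("high", 160)),
               "2 levels")
  expect_error(cox_hazard_ratio(times, rep(0, 160), grp), "no events")
})

test_that("roc_at_horizon equals brute-force concordance (exhaustive, n <= 50)", {
  brute_auc <- function(cases, controls) {
    s <- 0
    for (x in cases) for (y in controls)
      s <- s + (x > y) + 0.5 * (x == y)
    s / (length(cases) * length(controls))
  }
  # the worked small case: cases {3, 2}, controls {1, 2} -> 0.875
  marker <- c(3, 2, 1, 2)
  times <- c(0.5, 0.8, 5, 6); events <- c(1, 1, 0, 0)
  r <- roc_at_horizon(marker, times, events, horizon = 1, n_boot = 0)
  expect_equal(r$auc, 0.875)
  expect_equal(r$auc, brute_auc(c(3, 2), c(1, 2)))

  set.seed(33)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    marker <- sample(1:8, n, replace = TRUE)   # plenty of ties
    times <- rexp(n, 0.1); events <- rbinom(n, 1, 0.8)
    horizon <- quantile(times, 0.5, names = FALSE)
    case <- times <= horizon & events == 1
    control <- times > horizon
    if (!any(case) || !any(control)) next
    r <- roc_at_horizon(marker, times, events, horizon, n_boot = 0)
    expect_equal(r$auc, brute_auc(marker[case], marker[control]))
    expect_equal(r$n_excluded_censored, sum(times <= horizon & events == 0))
  }
})

test_that("roc_at_horizon: perfect marker, exclusions, CI behavior", {
  # perfect separation -> AUC exactly 1
  times <- c(rep(0.5, 10), rep(5, 10)); events <- rep(1, 20)
  marker <- c(rep(9, 10), rep(1, 10))
  r <- roc_at_horizon(marker, times, events, 1, n_boot = 200, seed = 4)
  expect_equal(r$auc, 1.0)
  expect_true(r$ci[1] <= 1 && r$ci[2] >= r$auc - 1e-12)

  # bootstrap CI is seeded-deterministic and contains the estimate
  set.seed(2); mk <- rnorm(60); tm <- rexp(60, 0.1); ev <- rbinom(60, 1, 0.9)
  a <- roc_at_horizon(mk, tm, ev, 5, n_boot = 300, seed = 11)
  b <- roc_at_horizon(mk, tm, ev, 5, n_boot = 300, seed = 11)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])

  expect_error(roc_at_horizon(mk, tm, ev, 1e6), "controls")
  expect_error(roc_at_horizon(mk, tm + 100, ev, 1), "cases")
})

test_that("pearson_chi2 reproduces the published cohort p-values exactly", {
  tabs <- utils::read.table(
    system.file("extdata", "published_contingency_tables.tsv",
                package = "lesionmap"),
    header = TRUE, sep = "\t")
  get <- function(v) {
    r <- tabs[tabs$variable == v, ]
    matrix(c(r$gbm_a, r$gbm_b, r$astro_a, r$astro_b), 2)
  }
  expect_equal(round(pearson_chi2(get("sex_male_vs_female"))$p, 3), 0.308)
  expect_equal(round(pearson_chi2(get("kps_ge80_vs_lt80"))$p, 3), 0.112)
  expect_equal(round(pearson_chi2(get("volume_lt40_vs_ge40"))$p, 3), 0.711)
  # the age split is printed as a bound (< 0.001)
  expect_lt(pearson_chi2(get("age_ge50_vs_lt50"))$p, 0.001)

  # homogeneous table: statistic 0, p 1
  h <- pearson_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(h$statistic, 0); expect_equal(h$p, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")

  # oracle: agrees with stats::chisq.test(correct = FALSE) on random tables
  set.seed(6)
  for (rep in 1:5) {
    tb <- matrix(rpois(4, 30) + 1, 2)
    expect_equal(pearson_chi2(tb)$p,
                 chisq.test(tb, correct = FALSE)$p.value, tolerance = 1e-12)
  }
})

test_that("two_sample_ttest: identity, degeneracy, scale invariance, power", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  same <- two_sample_ttest(x, x)
  expect_equal(same$statistic, 0); expect_equal(same$p, 1)

  const <- two_sample_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$p, 1)

  set.seed(9)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  r1 <- two_sample_ttest(a, b)
  r2 <- two_sample_ttest(a * 7, b * 7)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  # Student flavor via flag matches stats::t.test
  expect_equal(two_sample_ttest(a, b, equal_variance = TRUE)$p,
               t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)

  big <- two_sample_ttest(rnorm(200), rnorm(200, 1))
  expect_lt(big$p, 0.001)
})
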