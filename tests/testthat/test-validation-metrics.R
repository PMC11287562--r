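test_that("E/O ratio matches hand arithmetic and degenerates sensibly", {
  eo <- expected_observed_ratio(c(0.1, 0.2, 0.3), c(0, 1, 1))
  expect_equal(eo$E, 0.6)
  expect_equal(eo$O, 2)
  expect_equal(eo$ratio, 0.3)
  eo_w <- expected_observed_ratio(c(0.1, 0.2, 0.3), c(0, 1, 1),
                                  weights = c(2, 1, 1))
  expect_equal(eo_w$E, 0.7)
  expect_equal(eo_w$O, 2)
  expect_equal(eo_w$ratio, 0.35)
  # predictions equal to the 0/1 outcomes: perfectly calibrated sums
  expect_equal(expected_observed_ratio(c(0, 1, 1, 0), c(0, 1, 1, 0),
                                       weights = c(3, 1, 2, 5))$ratio, 1)
  expect_error(expected_observed_ratio(c(0.1, 0.2), c(0, 0)), "no observed cases")
  # E/O is NOT invariant to monotone transforms of the predictions
  expect_false(isTRUE(all.equal(
    expected_observed_ratio(c(0.1, 0.2, 0.3)^2, c(0, 1, 1))$ratio, 0.3)))
})

test_that("calibration slope recovers 1 under calibration and 0.5 under doubling", {
  set.seed(101)
  n <- 50000
  eta <- rnorm(n, -3, 1)
  p <- plogis(eta)
  y <- rbinom(n, 1, p)
  sl <- calibration_slope(p, y)
  expect_lt(abs(sl$slope - 1), 3 * sl$se)
  # predictions twice as extreme on the logit scale: slope near 0.5
  sl2 <- calibration_slope(plogis(2 * (eta + 3) - 3), y)
  expect_lt(abs(sl2$slope - 0.5), 3 * sl2$se)
  expect_error(calibration_slope(rep(0.2, 10), rep(c(0, 1), 5)), "constant")
  expect_error(calibration_slope(c(0.1, 0.2), c(1, 1)), "non-case")
})

test_that("quintile calibration conserves E and balances bins", {
  set.seed(7)
  n <- 2000
  p <- runif(n, 0.01, 0.3)
  y <- rbinom(n, 1, p)
  w <- runif(n, 0.5, 2)
  q <- quintile_calibration(p, y, w)
  expect_equal(sum(q$E), sum(w * p), tolerance = 1e-9)
  expect_equal(sum(q$O), sum(w * y), tolerance = 1e-9)
  # unit weights, unique predictions: bin sizes differ by at most one
  qu <- quintile_calibration(p, y)
  expect_lte(diff(range(qu$n)), 1)
  # under calibration every bin interval should usually cover 1; check the
  # coarse property that observed ratios are near 1 on average
  expect_lt(abs(mean(q$ratio) - 1), 0.25)
})

test_that("weighted AUC matches brute force, including ties and weights", {
  expect_equal(weighted_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0),
                            ci = "none")$auc, 0.75)
  # perfect separation and all-tied predictions
  expect_equal(weighted_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                            ci = "none")$auc, 1)
  expect_equal(weighted_auc(rep(0.3, 6), c(1, 0, 1, 0, 0, 1),
                            ci = "none")$auc, 0.5)
  expect_error(weighted_auc(c(0.2, 0.3), c(1, 1)), "non-case")
  set.seed(11)
  for (r in 1:10) {
    n <- sample(20:80, 1)
    p <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # heavy ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    w <- sample(c(0.5, 1, 2.5), n, replace = TRUE)
    expect_equal(weighted_auc(p, y, w, ci = "none")$auc, auc_brute(p, y, w),
                 tolerance = 1e-12)
  }
})

test_that("Harrell's C handles the worked censored example and brute force", {
  # perfect concordance: risk decreasing in event time
  expect_equal(harrell_c(c(0.9, 0.5, 0.2), c(1, 2, 3), c(TRUE, TRUE, TRUE),
                         ci = "none")$c_index, 1)
  # censored example worked by pair enumeration: two comparable pairs,
  # one concordant, one discordant
  expect_equal(harrell_c(c(0.5, 0.4, 0.3), c(2, 1, 3),
                         c(FALSE, TRUE, TRUE), ci = "none")$c_index, 0.5)
  expect_error(harrell_c(c(0.5, 0.4), c(1, 2), c(FALSE, FALSE), ci = "none"),
               "no comparable")
  set.seed(13)
  for (r in 1:10) {
    n <- sample(20:80, 1)
    p <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    tm <- sample(1:15, n, replace = TRUE)  # tied times occur
    ev <- runif(n) < 0.5
    if (!any(ev)) next
    w <- sample(c(0.5, 1, 3), n, replace = TRUE)
    expect_equal(harrell_c(p, tm, ev, w, ci = "none")$c_index,
                 cindex_brute(p, tm, ev, w), tolerance = 1e-12)
  }
})

test_that("concordance agrees with the survival package on tie-free data", {
  skip_if_not_installed("survival")
  set.seed(17)
  n <- 400
  p <- runif(n)
  tm <- rexp(n) + 0.1
  ev <- runif(n) < 0.6
  ours <- harrell_c(p, tm, ev, ci = "none")$c_index
  ref <- survival::concordance(survival::Surv(tm, ev) ~ p, reverse = TRUE)
  expect_equal(ours, unname(ref$concordance), tolerance = 1e-12)
})

test_that("AUC agrees with pROC on untied data", {
  skip_if_not_installed("pROC")
  set.seed(19)
  n <- 300
  p <- runif(n)
  y <- rbinom(n, 1, 0.3)
  ours <- weighted_auc(p, y, ci = "none")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("rank metrics are invariant to monotone transforms; calibration is not", {
  set.seed(23)
  n <- 200
  p <- runif(n, 0.01, 0.5)
  y <- rbinom(n, 1, p)
  tm <- rexp(n) + 0.1
  ev <- y == 1
  w <- runif(n, 0.5, 2)
  g <- function(x) plogis(3 * qlogis(x) + 1)  # strictly monotone
  expect_equal(weighted_auc(g(p), y, w, ci = "none")$auc,
               weighted_auc(p, y, w, ci = "none")$auc, tolerance = 1e-12)
  expect_equal(harrell_c(g(p), tm, ev, w, ci = "none")$c_index,
               harrell_c(p, tm, ev, w, ci = "none")$c_index, tolerance = 1e-12)
  s1 <- risk_stratification(p, y, w)
  s2 <- risk_stratification(g(p), y, w)
  expect_equal(s2$top_half_capture, s1$top_half_capture, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    expected_observed_ratio(g(p), y, w)$ratio,
    expected_observed_ratio(p, y, w)$ratio)))
  expect_false(isTRUE(all.equal(
    calibration_slope(g(p), y, w)$slope, calibration_slope(p, y, w)$slope)))
})

test_that("risk stratification counts thresholds, NPV and top-half capture", {
  st <- risk_stratification(c(0.01, 0.02, 0.04, 0.06), c(0, 0, 0, 1))
  expect_equal(st$thresholds$prop_below, c(0.25, 0.5, 0.75))
  expect_equal(st$thresholds$npv, c(1, 1, 1))
  # all outcomes false: NPV 1 at every non-empty threshold
  st0 <- risk_stratification(c(0.01, 0.02, 0.04, 0.06), c(0, 0, 0, 0))
  expect_true(all(st0$thresholds$npv == 1))
  # all cases in the top predicted-risk half
  st1 <- risk_stratification(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(st1$top_half_capture, 1)
  expect_error(risk_stratification(c(0.1, 0.2), c(0, 1),
                                   thresholds = c(0.05, 0.03)), "increasing")
  # age/gene breakdown covers every stratum
  st2 <- risk_stratification(c(0.01, 0.02, 0.04, 0.06), c(0, 0, 1, 1),
                             age_at_entry = c(25, 35, 45, 55),
                             gene = c("BRCA1", "BRCA1", "BRCA2", "BRCA2"))
  expect_setequal(unique(st2$subgroups$variable), c("age_group", "gene"))
})

test_that("unit-weight metrics equal their unweighted forms exactly", {
  set.seed(29)
  n <- 150
  p <- runif(n, 0.01, 0.4)
  y <- rbinom(n, 1, p)
  tm <- rexp(n) + 0.1
  ev <- y == 1
  ones <- rep(1, n)
  expect_equal(expected_observed_ratio(p, y, ones)$ratio,
               expected_observed_ratio(p, y)$ratio, tolerance = 1e-12)
  expect_equal(weighted_auc(p, y, ones, ci = "none")$auc,
               weighted_auc(p, y, ci = "none")$auc, tolerance = 1e-12)
  expect_equal(harrell_c(p, tm, ev, ones, ci = "none")$c_index,
               harrell_c(p, tm, ev, ci = "none")$c_index, tolerance = 1e-12)
  expect_equal(calibration_slope(p, y, ones)$slope,
               calibration_slope(p, y)$slope, tolerance = 1e-12)
})
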