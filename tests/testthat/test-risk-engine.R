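test_that("hazard_at_age multiplies enabled relative hazards onto the baseline", {
  m <- hazard_model(c(20, 80), bc_incidence = 0.005, mortality = 0,
                    log_rr_gene = list(BRCA1 = log(8), BRCA2 = 0),
                    log_rr_prs = log(1.5))
  p <- risk_profile("BRCA1", prs_z = 1)
  v <- model_variant("gene+prs", use_gene = TRUE, use_prs = TRUE)
  expect_equal(hazard_at_age(p, v, m, 45), 0.005 * 8 * 1.5)

  # null variant: baseline only, whatever the profile
  expect_equal(hazard_at_age(p, model_variant("null"), m, 45), 0.005)
  # zero PRS contributes a factor of one
  p0 <- risk_profile("BRCA1", prs_z = 0)
  expect_equal(hazard_at_age(p0, v, m, 45),
               hazard_at_age(p0, model_variant("g", use_gene = TRUE), m, 45))
  # log-additivity: doubling every relative hazard doubles the hazard
  m2 <- hazard_model(c(20, 80), 0.005, 0,
                     log_rr_gene = list(BRCA1 = log(8) + log(2), BRCA2 = 0),
                     log_rr_prs = log(1.5))
  v2 <- model_variant("g", use_gene = TRUE)
  expect_equal(hazard_at_age(p, v2, m2, 45),
               2 * hazard_at_age(p, v2, m, 45))
  expect_error(hazard_at_age(p, v, m, 81), "age grid")
})

test_that("absolute_risk matches closed forms for constant hazards", {
  p <- risk_profile("BRCA1")
  v <- model_variant("null")
  # no competing mortality
  m <- flat_model(lambda = 0.02, mu = 0)
  expect_equal(absolute_risk(p, v, m, 45, 50), 1 - exp(-0.1),
               tolerance = 1e-12)
  # with competing mortality: lam/(lam+mu) * (1 - exp(-(lam+mu)T))
  m2 <- flat_model(lambda = 0.02, mu = 0.01)
  expect_equal(absolute_risk(p, v, m2, 45, 50),
               (0.02 / 0.03) * (1 - exp(-0.15)), tolerance = 1e-12)
  # zero hazard: zero risk over any window
  m0 <- flat_model(lambda = 0, mu = 0.01)
  expect_equal(absolute_risk(p, v, m0, 30, 60), 0)
  expect_error(absolute_risk(p, v, m, 70, 85), "maximum age")
  expect_equal(absolute_risk(p, v, m, 75, 85, clamp = TRUE),
               absolute_risk(p, v, m, 75, 80))
  expect_error(absolute_risk(p, v, m, 50, 45), "below end_age")
})

test_that("absolute_risk is monotone in the window and the relative hazards", {
  m <- default_hazard_model()
  p <- risk_profile("BRCA2", prs_z = 0.7,
                    qrf = c(parity = "parous", mht = "current", bmi = "normal"),
                    fh_score = 1)
  v <- model_variant("full", use_gene = TRUE, use_prs = TRUE,
                     use_qrf = TRUE, use_fh = TRUE)
  ends <- seq(41, 65, by = 2)
  risks <- vapply(ends, function(e) absolute_risk(p, v, m, 40, e), numeric(1))
  expect_true(all(diff(risks) > 0))
  # raising any relative hazard raises the risk
  p_hi <- risk_profile("BRCA2", prs_z = 1.5,
                       qrf = c(parity = "parous", mht = "current", bmi = "normal"),
                       fh_score = 2)
  expect_gt(absolute_risk(p_hi, v, m, 40, 45), absolute_risk(p, v, m, 40, 45))
  # bounded by the censoring-free cumulative hazard
  lam <- oracle_lambda(m, "BRCA2", 0.7,
                       c(parity = "parous", mht = "current", bmi = "normal"), 1)
  cumhaz <- sum(lam[5:9] * 5)  # bands [40,45) .. [60,65)
  expect_lte(absolute_risk(p, v, m, 40, 65), 1 - exp(-cumhaz))
})

test_that("risks are consistent across band edges (Chapman-Kolmogorov)", {
  m <- default_hazard_model()
  v <- model_variant("full", use_gene = TRUE, use_prs = TRUE,
                     use_qrf = TRUE, use_fh = TRUE)
  qrf <- c(parity = "parous", mht = "never", bmi = "normal")
  for (p in list(risk_profile("BRCA1", prs_z = -1, qrf = qrf, fh_score = 0),
                 risk_profile("BRCA2", prs_z = 1.2, qrf = qrf, fh_score = 2))) {
    for (w in list(c(38, 45, 51), c(40, 50, 60), c(22.5, 40, 79.5))) {
      direct <- absolute_risk(p, v, m, w[1], w[3])
      split <- absolute_risk(p, v, m, w[1], w[2]) +
        event_free_survival(p, v, m, w[1], w[2]) *
          absolute_risk(p, v, m, w[2], w[3])
      expect_equal(split, direct, tolerance = 1e-12)
    }
  }
})

test_that("closed-form risk equals fine-grid numerical quadrature", {
  m <- default_hazard_model()
  v <- model_variant("full", use_gene = TRUE, use_prs = TRUE,
                     use_qrf = TRUE, use_fh = TRUE)
  p <- risk_profile("BRCA1", prs_z = 0.8,
                    qrf = c(parity = "nulliparous", mht = "current", bmi = "obese"),
                    fh_score = 1)
  lam_b <- oracle_lambda(m, "BRCA1", 0.8,
                         c(parity = "nulliparous", mht = "current", bmi = "obese"), 1)
  start <- 43.2
  end <- 56.7
  h <- 0.001
  edges <- c(start, m$age_breaks[m$age_breaks > start & m$age_breaks < end], end)
  S0 <- 1
  quad <- 0
  for (s in seq_len(length(edges) - 1L)) {
    k <- findInterval(edges[s], m$age_breaks)
    tot <- lam_b[k] + m$mortality[k]
    len <- edges[s + 1L] - edges[s]
    nstep <- 2L * ceiling(len / h / 2)           # even count for Simpson
    u <- seq(0, len, length.out = nstep + 1L)
    f <- lam_b[k] * S0 * exp(-tot * u)
    wts <- c(1, rep(c(4, 2), length.out = nstep - 1L), 1)
    quad <- quad + sum(wts * f) * (len / nstep) / 3
    S0 <- S0 * exp(-tot * (edges[s + 1L] - edges[s]))
  }
  expect_equal(absolute_risk(p, v, m, start, end), quad, tolerance = 1e-9)
})

test_that("predict_cohort windows, truncation and variant handling behave", {
  m <- default_hazard_model()
  rec <- rbind(make_record("A", baseline_age = 40, last_followup_age = 42),
               make_record("B", baseline_age = 40, last_followup_age = 49))
  prep <- prepare_cohort(rec)$cohort
  full <- model_variant("full", use_gene = TRUE, use_prs = TRUE,
                        use_qrf = TRUE, use_fh = TRUE)
  pf <- predict_cohort(prep, m, list(full))
  pc <- predict_cohort(prep, m, list(full), predict_to_censoring = TRUE)
  # A censored at 42, inside the window: truncated risk strictly smaller
  expect_lt(pc$risks[1, 1], pf$risks[1, 1])
  # B reaches the administrative cap: identical under both settings
  expect_equal(pc$risks[2, 1], pf$risks[2, 1])
  # variants differing only in use_prs agree for a woman with prs_z = 0
  v1 <- model_variant("g", use_gene = TRUE)
  v2 <- model_variant("gp", use_gene = TRUE, use_prs = TRUE)
  pz <- predict_cohort(prep, m, list(v1, v2))
  expect_equal(pz$risks[, "g"], pz$risks[, "gp"])
  expect_error(predict_cohort(prep, m, list()), "at least one")
  # long export keyed by woman and variant
  long <- as.data.frame(pz)
  expect_equal(nrow(long), 2L * nrow(prep))
  expect_setequal(unique(long$variant), c("g", "gp"))
})

test_that("hazard model JSON round-trips exactly", {
  m <- default_hazard_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_hazard_model(m, f)
  m2 <- read_hazard_model(f)
  expect_equal(m2, m)
})
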