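test_that("standardize_prs applies the published constants", {
  expect_equal(standardize_prs(-0.424), 0)
  expect_equal(standardize_prs(0.187), 1)
  expect_equal(standardize_prs(-1.035), -1)
  expect_error(standardize_prs(0.1, sd = 0), "positive")
  expect_error(standardize_prs(0.1, sd = -1), "positive")
})

test_that("seeded cohorts are reproducible and prefix-stable", {
  cfg <- simulation_config(n_women = 200, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # per-woman substreams: growing the cohort does not perturb earlier women
  small <- simulate_cohort(simulation_config(n_women = 80, seed = 42))
  expect_identical(small, a[seq_len(80), ])
  # simulate_cohort leaves the caller's RNG stream untouched
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(simulate_cohort(simulation_config(n_women = 5, seed = 1)))
  expect_identical(runif(3), before)
})

test_that("zero hazards and zero rates produce event-free records", {
  m0 <- hazard_model(seq(20, 80, 5), bc_incidence = 0, mortality = 0,
                     log_rr_gene = list(BRCA1 = 0, BRCA2 = 0), log_rr_prs = 0,
                     log_rr_qrf = list(
                       parity = c(nulliparous = 0, parous = 0),
                       mht = c(never = 0, past = 0, current = 0),
                       bmi = c(normal = 0, overweight = 0, obese = 0)),
                     log_rr_fh = 0)
  cfg <- simulation_config(n_women = 300, seed = 3, hazard_model = m0,
                           dropout_rate = 0, mastectomy_rate = 0,
                           rrso_rate = 0)
  coh <- simulate_cohort(cfg)
  expect_true(all(is.na(coh$bc_age)))
  expect_true(all(is.na(coh$death_age)))
  expect_true(all(is.na(coh$mastectomy_age)))
  expect_equal(coh$last_followup_age, coh$baseline_age + 8)
})

test_that("event ages respect record invariants", {
  coh <- simulate_cohort(simulation_config(n_women = 2000, seed = 5))
  for (col in c("bc_age", "death_age", "mastectomy_age", "rrso_age")) {
    v <- coh[[col]]
    expect_true(all(v[!is.na(v)] >= coh$baseline_age[!is.na(v)]))
    expect_true(all(v[!is.na(v)] < 80))
  }
  expect_true(all(coh$last_followup_age >= coh$baseline_age))
  expect_true(all(coh$prs_z == standardize_prs(coh$prs_raw)))
})

test_that("simulated event fractions match the constant-hazard closed form", {
  # flat individual hazard of 0.05/yr, no competing events
  m <- hazard_model(seq(20, 80, 5), bc_incidence = 0.05, mortality = 0,
                    log_rr_gene = list(BRCA1 = 0, BRCA2 = 0), log_rr_prs = 0)
  p <- risk_profile("BRCA1")
  set.seed(314)
  n <- 20000
  u <- matrix(runif(6 * n), n)
  ages <- vapply(seq_len(n), function(i) {
    simulate_event_times(p, 40, m, u = u[i, ])$bc_age
  }, numeric(1))
  frac <- mean(!is.na(ages) & ages < 45)
  target <- 1 - exp(-0.25)
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(frac - target), 3 * se)
  expect_error(simulate_event_times(p, 15, m), "age grid")
})

test_that("ascertainment enriches the cohort in family history", {
  cfg <- simulation_config(n_women = 20000, seed = 8)
  coh <- simulate_cohort(cfg)
  pop_mean <- cfg$fh_pop_mean
  se <- sd(coh$fh_score) / sqrt(nrow(coh))
  expect_gt(mean(coh$fh_score), pop_mean + 3 * se)
})

test_that("subcohort inclusion follows the configured logistic truth", {
  coh <- simulate_cohort(simulation_config(n_women = 20000, seed = 12))
  # degenerate: huge intercept -> everyone included
  all_in <- simulate_subcohort_inclusion(
    coh, c(intercept = 30, age = 0, followup = 0, bc = 0,
           bc_age = 0, bc_followup = 0), seed = 12)
  expect_true(all(all_in$included))
  # intercept 0 -> inclusion probability one half
  half <- simulate_subcohort_inclusion(
    coh, c(intercept = 0, age = 0, followup = 0, bc = 0,
           bc_age = 0, bc_followup = 0), seed = 12)
  frac <- mean(half$included)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(coh)))
  # positive BC coefficient -> cases included more often than non-cases
  sel <- simulate_subcohort_inclusion(
    coh, c(intercept = -1, age = 0, followup = 0, bc = 3,
           bc_age = 0, bc_followup = 0), seed = 12)
  bc <- derive_follow_up(sel)$event == "BC"
  expect_gt(mean(sel$included[bc]), mean(sel$included[!bc]))
})

test_that("cohort CSV round-trips to identical records", {
  coh <- simulate_cohort(simulation_config(n_women = 150, seed = 21,
    inclusion_model_truth = c(intercept = 1, age = 0, followup = 0,
                              bc = 1, bc_age = 0, bc_followup = 0)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_equal(back, coh)
})
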