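#' Standardize a raw polygenic risk score
#'
#' Converts a raw 313-SNP polygenic score to SD units using fixed population
#' constants (defaults: mean -0.424, SD 0.611).
#'
#' @param raw raw score(s).
#' @param mean,sd standardization constants; `sd` must be positive.
#' @return standardized score(s): `(raw - mean) / sd`.
#' @export
standardize_prs <- function(raw, mean = -0.424, sd = 0.611) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("sd must be a positive number")
  }
  (raw - mean) / sd
}

#' Synthetic-cohort simulation configuration
#'
#' Defines the study conditions the generator emulates: a clinic-ascertained
#' BRCA1/2 carrier cohort with family-history-enriched entry, raw polygenic
#' scores on the published scale, multiplicative hazards (the generator
#' truth), competing censoring events at constant per-year rates, and
#' optional outcome-dependent subcohort inclusion.
#'
#' @param n_women cohort size after ascertainment.
#' @param seed integer seed; every draw is a deterministic function of
#'   `(seed, woman index)`, so record `i` is identical across cohort sizes.
#' @param hazard_model generator-truth [hazard_model()].
#' @param prs_mean,prs_sd raw-scale PRS distribution (so the standardized
#'   PRS is standard normal under the matching constants).
#' @param baseline_age list `min`, `max`, `shape1`, `shape2`: entry ages are
#'   `min + (max - min) * Beta(shape1, shape2)`.
#' @param brca1_fraction proportion of BRCA1 carriers.
#' @param countries named vector of country frequencies.
#' @param qrf_freqs named list: factor -> named category frequencies; the
#'   names must match the hazard model's QRF table.
#' @param fh_pop_mean population mean of the Poisson-distributed count of
#'   affected first-degree relatives before ascertainment.
#' @param fh_ascertainment_intercept,fh_ascertainment_strength log-odds of
#'   cohort entry: `plogis(intercept + strength * fh_score)`. A positive
#'   strength enriches the cohort in family history.
#' @param dropout_rate,mastectomy_rate,rrso_rate constant per-year rates of
#'   loss to follow-up, bilateral risk-reducing mastectomy and risk-reducing
#'   salpingo-oophorectomy.
#' @param dcis_fraction probability that an incident BC is DCIS.
#' @param followup_years_max administrative maximum follow-up in years.
#' @param inclusion_model_truth optional named coefficients
#'   (`intercept`, `age`, `followup`, `bc`, `bc_age`, `bc_followup`) for
#'   outcome-dependent subcohort inclusion; `NULL` includes everyone.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_women,
                              seed = 1L,
                              hazard_model = default_hazard_model(),
                              prs_mean = -0.424,
                              prs_sd = 0.611,
                              baseline_age = list(min = 20, max = 70,
                                                  shape1 = 1.8, shape2 = 2.6),
                              brca1_fraction = 0.54,
                              countries = c(DE = 0.25, UK = 0.20, FR = 0.20,
                                            NL = 0.20, AT = 0.05, PL = 0.10),
                              qrf_freqs = list(
                                parity = c(nulliparous = 0.35, parous = 0.65),
                                mht = c(never = 0.70, past = 0.18, current = 0.12),
                                bmi = c(normal = 0.55, overweight = 0.30, obese = 0.15)),
                              fh_pop_mean = 0.3,
                              fh_ascertainment_intercept = -0.4,
                              fh_ascertainment_strength = 0.9,
                              dropout_rate = 0.02,
                              mastectomy_rate = 0.015,
                              rrso_rate = 0.025,
                              dcis_fraction = 0.12,
                              followup_years_max = 8,
                              inclusion_model_truth = NULL) {
  stopifnot(n_women >= 1, n_women == round(n_women))
  if (prs_sd <= 0) stop("prs_sd must be positive")
  rates <- c(dropout_rate, mastectomy_rate, rrso_rate)
  if (any(rates < 0)) stop("per-year rates must be >= 0")
  if (dcis_fraction < 0 || dcis_fraction > 1) stop("dcis_fraction must be in [0, 1]")
  stopifnot(inherits(hazard_model, "hazard_model"))
  if (baseline_age$min < hazard_model$age_breaks[1L] ||
      baseline_age$max >= hazard_model$max_age) {
    stop("baseline age range must lie inside the hazard model's age grid")
  }
  for (f in names(qrf_freqs)) {
    if (!f %in% names(hazard_model$log_rr_qrf)) {
      stop("QRF '", f, "' has no relative-hazard table in the model")
    }
    bad <- setdiff(names(qrf_freqs[[f]]), names(hazard_model$log_rr_qrf[[f]]))
    if (length(bad)) stop("QRF '", f, "' level(s) missing from model: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(inclusion_model_truth)) {
    need <- c("intercept", "age", "followup", "bc", "bc_age", "bc_followup")
    if (!all(need %in% names(inclusion_model_truth))) {
      stop("inclusion_model_truth needs coefficients: ",
           paste(need, collapse = ", "))
    }
  }
  structure(list(
    n_women = as.integer(n_women), seed = as.integer(seed),
    hazard_model = hazard_model, prs_mean = prs_mean, prs_sd = prs_sd,
    baseline_age = baseline_age, brca1_fraction = brca1_fraction,
    countries = countries / sum(countries), qrf_freqs = qrf_freqs,
    fh_pop_mean = fh_pop_mean,
    fh_ascertainment_intercept = fh_ascertainment_intercept,
    fh_ascertainment_strength = fh_ascertainment_strength,
    dropout_rate = dropout_rate, mastectomy_rate = mastectomy_rate,
    rrso_rate = rrso_rate, dcis_fraction = dcis_fraction,
    followup_years_max = followup_years_max,
    inclusion_model_truth = inclusion_model_truth
  ), class = "simulation_config")
}

# Inverse-transform draw of event ages from piecewise-constant individual
# rates, starting at `start`. rate_mat: n x nb; u: n uniforms. Returns the
# event age, or Inf when no event occurs before the end of the grid.
.draw_piecewise_times <- function(rate_mat, breaks, start, u) {
  n <- nrow(rate_mat)
  nb <- ncol(rate_mat)
  lower <- matrix(breaks[-length(breaks)], n, nb, byrow = TRUE)
  upper <- matrix(breaks[-1L], n, nb, byrow = TRUE)
  L <- pmax(0, upper - pmax(start, lower))
  A <- rate_mat * L
  UTD <- matrix(0, nb, nb)
  UTD[upper.tri(UTD, diag = TRUE)] <- 1
  cum <- A %*% UTD                      # inclusive cumulative hazard per band
  H <- -log(u)
  k <- rowSums(cum < H) + 1L            # first band whose cumulative reaches H
  age <- rep(Inf, n)
  hit <- k <= nb
  if (any(hit)) {
    i <- which(hit)
    prev <- ifelse(k[i] > 1L, cum[cbind(i, pmax(k[i] - 1L, 1L))], 0)
    rate <- rate_mat[cbind(i, k[i])]
    band_start <- pmax(start[i], breaks[k[i]])
    age[i] <- band_start + (H[i] - prev) / rate
  }
  age
}

#' Simulate latent event ages for one woman
#'
#' Draws the latent breast-cancer age by inverse-transform sampling from the
#' woman's piecewise-constant hazard (full generator truth: gene, PRS, QRFs
#' and FH all active), the latent death age from the model's competing
#' mortality, and mastectomy / RRSO / dropout ages from constant per-year
#' rates. Events falling at or beyond the model's maximum age are absent
#' (`NA`).
#'
#' @param profile a [risk_profile()].
#' @param baseline_age entry age, inside the model's age grid.
#' @param model generator-truth [hazard_model()].
#' @param rates named list of constant per-year rates `mastectomy`, `rrso`,
#'   `dropout` (missing entries default to 0).
#' @param dcis_fraction probability an incident BC is DCIS.
#' @param u optional vector of 6 uniforms (BC, death, mastectomy, RRSO,
#'   dropout, DCIS); drawn from the current RNG stream when `NULL`.
#' @return list with `bc_age`, `bc_is_dcis`, `death_age`, `mastectomy_age`,
#'   `rrso_age`, `dropout_age` (ages in years, `NA` when absent).
#' @export
simulate_event_times <- function(profile, baseline_age, model,
                                 rates = list(), dcis_fraction = 0, u = NULL) {
  stopifnot(inherits(model, "hazard_model"))
  if (baseline_age < model$age_breaks[1L] || baseline_age >= model$max_age) {
    stop("baseline_age outside the model's age grid")
  }
  if (is.null(u)) u <- stats::runif(6L)
  stopifnot(length(u) == 6L)
  full <- model_variant("truth", use_gene = TRUE, use_prs = TRUE,
                        use_qrf = TRUE, use_fh = TRUE)
  lam <- .hazard_matrix(.profile_df(profile), full, model)
  mu <- matrix(model$mortality, 1L)
  bc <- .draw_piecewise_times(lam, model$age_breaks, baseline_age, u[1L])
  death <- .draw_piecewise_times(mu, model$age_breaks, baseline_age, u[2L])
  const_age <- function(rate, ui) {
    if (rate > 0) baseline_age - log(ui) / rate else Inf
  }
  r <- function(nm) if (!is.null(rates[[nm]])) rates[[nm]] else 0
  mast <- const_age(r("mastectomy"), u[3L])
  rrso <- const_age(r("rrso"), u[4L])
  drop <- const_age(r("dropout"), u[5L])
  cap <- function(a) if (is.finite(a) && a < model$max_age) a else NA_real_
  list(
    bc_age = cap(bc),
    bc_is_dcis = if (is.finite(bc) && bc < model$max_age) u[6L] < dcis_fraction else FALSE,
    death_age = cap(death),
    mastectomy_age = cap(mast),
    rrso_age = cap(rrso),
    dropout_age = cap(drop)
  )
}

#' Simulate a clinic-ascertained carrier cohort
#'
#' Generates `config$n_women` records. Per woman, within her own seeded
#' substream: candidate profiles (PRS, QRF levels, FH score) are drawn and
#' accepted with probability increasing in the FH score (family-history
#' enriched ascertainment); entry age, gene, country and latent event ages
#' follow. Event histories are produced by the same piecewise-constant
#' machinery the risk engine integrates, so analytic risks are the exact
#' expectation of simulated outcomes.
#'
#' @param config a [simulation_config()].
#' @return data frame, one row per woman, with identifier, country, gene,
#'   baseline age, raw and standardized PRS, QRF levels, FH score, event ages
#'   (`NA` when absent), `last_followup_age` and `included` flag.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_women
  model <- config$hazard_model
  qrf_names <- names(config$qrf_freqs)
  nq <- length(qrf_names)

  z <- numeric(n)
  uq <- matrix(0, n, max(nq, 1L))
  fh <- integer(n)
  uev <- matrix(0, n, 9L)
  .with_preserved_seed({
    for (i in seq_len(n)) {
      set.seed(.substream_seed(config$seed, i, salt = 1L))
      repeat {
        zi <- stats::rnorm(1L)
        u1 <- stats::runif(nq + 2L)
        f <- stats::qpois(u1[nq + 1L], config$fh_pop_mean)
        p <- stats::plogis(config$fh_ascertainment_intercept +
                             config$fh_ascertainment_strength * f)
        if (u1[nq + 2L] <= p) break
      }
      z[i] <- zi
      if (nq) uq[i, ] <- u1[seq_len(nq)]
      fh[i] <- f
      uev[i, ] <- stats::runif(9L)
    }
  })

  ba <- config$baseline_age
  baseline_age <- ba$min + (ba$max - ba$min) *
    stats::qbeta(uev[, 1L], ba$shape1, ba$shape2)
  gene <- ifelse(uev[, 2L] < config$brca1_fraction,
                 names(model$log_rr_gene)[1L], names(model$log_rr_gene)[2L])
  cc <- cumsum(config$countries)
  country <- names(config$countries)[
    1L + rowSums(outer(uev[, 3L], cc[-length(cc)], ">"))]
  prs_raw <- config$prs_mean + config$prs_sd * z
  prs_z <- standardize_prs(prs_raw, config$prs_mean, config$prs_sd)

  df <- data.frame(
    id = sprintf("W%06d", seq_len(n)),
    country = country, gene = gene, baseline_age = baseline_age,
    prs_raw = prs_raw, prs_z = prs_z, stringsAsFactors = FALSE
  )
  for (j in seq_len(nq)) {
    freqs <- config$qrf_freqs[[j]]
    cf <- cumsum(freqs) / sum(freqs)
    lev <- 1L + rowSums(outer(uq[, j], cf[-length(cf)], ">"))
    df[[paste0("qrf_", qrf_names[j])]] <- names(freqs)[lev]
  }
  df$fh_score <- fh

  full <- model_variant("truth", use_gene = TRUE, use_prs = TRUE,
                        use_qrf = TRUE, use_fh = TRUE)
  lam <- .hazard_matrix(df, full, model)
  bc <- .draw_piecewise_times(lam, model$age_breaks, baseline_age, uev[, 4L])
  mu_mat <- matrix(model$mortality, n, .n_bands(model), byrow = TRUE)
  death <- .draw_piecewise_times(mu_mat, model$age_breaks, baseline_age, uev[, 5L])
  const_draw <- function(rate, u) {
    if (rate > 0) baseline_age - log(u) / rate else rep(Inf, n)
  }
  mast <- const_draw(config$mastectomy_rate, uev[, 6L])
  rrso <- const_draw(config$rrso_rate, uev[, 7L])
  dropout <- const_draw(config$dropout_rate, uev[, 8L])
  cap <- function(a) ifelse(is.finite(a) & a < model$max_age, a, NA_real_)

  df$bc_age <- cap(bc)
  df$bc_is_dcis <- !is.na(df$bc_age) & uev[, 9L] < config$dcis_fraction
  df$death_age <- cap(death)
  df$mastectomy_age <- cap(mast)
  df$rrso_age <- cap(rrso)
  df$last_followup_age <- pmin(baseline_age + pmin(dropout - baseline_age,
                                                   config$followup_years_max),
                               model$max_age)
  df$included <- TRUE
  if (!is.null(config$inclusion_model_truth)) {
    df <- simulate_subcohort_inclusion(df, config$inclusion_model_truth,
                                       seed = config$seed)
  }
  df
}

#' Simulate outcome-dependent subcohort inclusion
#'
#' Draws the `included` flag per woman from a Bernoulli whose logit is linear
#' in baseline age, observed follow-up duration, incident BC status, and the
#' BC-by-age and BC-by-follow-up interactions. Used to exercise the
#' inverse-probability weighting scheme: positive BC coefficients make
#' inclusion non-random with respect to the outcome.
#'
#' @param records cohort data frame (as from [simulate_cohort()]).
#' @param coefficients named vector/list with `intercept`, `age`, `followup`,
#'   `bc`, `bc_age`, `bc_followup`.
#' @param seed integer; per-woman substreams as in [simulate_cohort()].
#' @return `records` with the `included` column set.
#' @export
simulate_subcohort_inclusion <- function(records, coefficients, seed = 1L) {
  co <- as.list(coefficients)
  fu <- derive_follow_up(records)
  bc <- as.numeric(fu$event == "BC")
  followup <- fu$exit_age - records$baseline_age
  eta <- co$intercept + co$age * records$baseline_age +
    co$followup * followup + co$bc * bc +
    co$bc_age * bc * records$baseline_age +
    co$bc_followup * bc * followup
  p <- stats::plogis(eta)
  n <- nrow(records)
  u <- numeric(n)
  .with_preserved_seed({
    for (i in seq_len(n)) {
      set.seed(.substream_seed(seed, i, salt = 2L))
      u[i] <- stats::runif(1L)
    }
  })
  records$included <- u <= p
  records
}

#' Read or write a cohort CSV
#'
#' One row per woman, absent events as empty cells. Numeric columns are
#' written with full double precision so a written-and-reread cohort
#' reproduces in-memory results exactly.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @return `read_cohort_csv` returns the cohort data frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (j in names(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  num <- c("baseline_age", "prs_raw", "prs_z", "bc_age", "death_age",
           "mastectomy_age", "rrso_age", "last_followup_age")
  for (j in intersect(num, names(df))) df[[j]] <- as.numeric(df[[j]])
  if ("bc_is_dcis" %in% names(df)) {
    df$bc_is_dcis <- as.logical(df$bc_is_dcis)
    df$bc_is_dcis[is.na(df$bc_is_dcis)] <- FALSE
  }
  if ("included" %in% names(df)) df$included <- as.logical(df$included)
  if ("fh_score" %in% names(df)) df$fh_score <- as.integer(df$fh_score)
  df
}
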