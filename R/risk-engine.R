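#' Individual risk-factor profile
#'
#' @param gene gene label, matching a name in the model's `log_rr_gene`.
#' @param prs_z standardized polygenic risk score in SD units.
#' @param qrf named character vector of questionnaire risk factor levels,
#'   e.g. `c(parity = "parous", mht = "never", bmi = "normal")`.
#' @param fh_score number of affected first-degree relatives.
#' @param prs_raw optional raw (unstandardized) polygenic score.
#' @return an object of class `risk_profile`.
#' @export
risk_profile <- function(gene, prs_z = 0, qrf = character(), fh_score = 0,
                         prs_raw = NA_real_) {
  stopifnot(length(gene) == 1L, length(prs_z) == 1L, is.finite(prs_z))
  if (fh_score < 0 || fh_score != round(fh_score)) {
    stop("fh_score must be a non-negative integer")
  }
  structure(list(gene = as.character(gene), prs_z = as.numeric(prs_z),
                 prs_raw = as.numeric(prs_raw), qrf = qrf,
                 fh_score = as.integer(fh_score)),
            class = "risk_profile")
}

# One-row data frame view of a profile, matching the cohort column layout.
.profile_df <- function(profile) {
  stopifnot(inherits(profile, "risk_profile"))
  df <- data.frame(gene = profile$gene, prs_z = profile$prs_z,
                   fh_score = profile$fh_score, stringsAsFactors = FALSE)
  for (f in names(profile$qrf)) df[[paste0("qrf_", f)]] <- unname(profile$qrf[[f]])
  df
}

#' Individual hazard at a given age
#'
#' The per-year breast-cancer hazard \eqn{\lambda(t)} for one woman under a
#' model variant: the baseline incidence of the age band containing `age`
#' multiplied by the exponentiated log relative hazards of every factor the
#' variant enables.
#'
#' @param profile a [risk_profile()].
#' @param variant a [model_variant()].
#' @param model a [hazard_model()].
#' @param age age in years, inside the model's age grid.
#' @return per-year rate (numeric scalar, or vector if `age` is a vector).
#' @export
hazard_at_age <- function(profile, variant, model, age) {
  stopifnot(inherits(model, "hazard_model"), inherits(variant, "model_variant"))
  k <- .band_index(age, model)
  lp <- .log_rr_matrix(.profile_df(profile), variant, model)
  unname(model$bc_incidence[k] * exp(lp[1L, k]))
}

# Vectorized competing-risk window integral on the piecewise-constant grid.
# lam: n x nb cause-specific BC hazards; mu: per-band mortality; start/end:
# length-n window edges. Returns risk (cumulative incidence of BC in the
# window) and surv (probability alive and BC-free at the window end), both
# conditional on being alive and BC-free at `start`. Closed form per band:
# contribution S(a) * lam/(lam+mu) * (1 - exp(-(lam+mu) L)).
.window_risk <- function(lam, mu, breaks, start, end) {
  n <- nrow(lam)
  nb <- ncol(lam)
  lower <- matrix(breaks[-length(breaks)], n, nb, byrow = TRUE)
  upper <- matrix(breaks[-1L], n, nb, byrow = TRUE)
  L <- pmax(0, pmin(end, upper) - pmax(start, lower))
  tot <- lam + matrix(mu, n, nb, byrow = TRUE)
  A <- tot * L
  # cumulative hazard before each band: A %*% strict upper-triangular ones
  UT <- matrix(0, nb, nb)
  UT[upper.tri(UT)] <- 1
  S_before <- exp(-(A %*% UT))
  frac <- ifelse(tot > 0, lam / tot, 0)
  contrib <- S_before * frac * (1 - exp(-A))
  list(risk = rowSums(contrib), surv = exp(-rowSums(A)))
}

#' Absolute risk over an age window
#'
#' Cumulative incidence of breast cancer between `start_age` and `end_age`,
#' conditional on being alive and BC-free at `start_age`, with non-BC
#' mortality as the competing event:
#' \deqn{\int_{s}^{e} \lambda(u)\,
#'   e^{-\int_s^u \lambda(v) + \mu(v)\,dv}\, du,}
#' evaluated in closed form band by band on the piecewise-constant grid.
#'
#' @inheritParams hazard_at_age
#' @param start_age,end_age window edges in years; `start_age < end_age`.
#' @param clamp if `TRUE`, an `end_age` beyond the model's maximum age is
#'   truncated to it instead of raising an error.
#' @return probability in \[0, 1\].
#' @export
absolute_risk <- function(profile, variant, model, start_age, end_age,
                          clamp = FALSE) {
  stopifnot(inherits(model, "hazard_model"))
  if (end_age > model$max_age) {
    if (!clamp) stop("end_age exceeds the model's maximum age (",
                     model$max_age, "); use clamp = TRUE to truncate")
    end_age <- model$max_age
  }
  if (start_age < model$age_breaks[1L]) stop("start_age below the age grid")
  if (start_age >= end_age) stop("start_age must be below end_age")
  lam <- .hazard_matrix(.profile_df(profile), variant, model)
  unname(.window_risk(lam, model$mortality, model$age_breaks,
                      start_age, end_age)$risk)
}

#' @describeIn absolute_risk probability of being alive and breast-cancer
#'   free at `end_age` given alive and BC-free at `start_age`.
#' @export
event_free_survival <- function(profile, variant, model, start_age, end_age,
                                clamp = FALSE) {
  stopifnot(inherits(model, "hazard_model"))
  if (end_age > model$max_age) {
    if (!clamp) stop("end_age exceeds the model's maximum age")
    end_age <- model$max_age
  }
  if (start_age >= end_age) stop("start_age must be below end_age")
  lam <- .hazard_matrix(.profile_df(profile), variant, model)
  unname(.window_risk(lam, model$mortality, model$age_breaks,
                      start_age, end_age)$surv)
}

# n x nb matrix of individual BC hazards for a cohort data frame.
.hazard_matrix <- function(df, variant, model) {
  lp <- .log_rr_matrix(df, variant, model)
  matrix(model$bc_incidence, nrow(df), .n_bands(model), byrow = TRUE) * exp(lp)
}

#' Fixed-horizon risk predictions for a prepared cohort
#'
#' Predicts, for every woman and every variant, the absolute BC risk over the
#' landmarked window `[baseline + landmark, baseline + landmark + horizon)`,
#' clamped at the model's maximum age. With `predict_to_censoring = TRUE`
#' (the practice used for calibration), unaffected women censored inside the
#' window have their window truncated at the censoring age, so that the sum
#' of predictions matches the expected number of observable cases.
#'
#' @param prepared data frame from [prepare_cohort()] (needs `baseline_age`,
#'   `exit_age`, `event` and the risk-factor columns).
#' @param model a [hazard_model()].
#' @param variants list of [model_variant()]s.
#' @param landmark years after baseline at which prediction starts.
#' @param horizon prediction horizon in years.
#' @param predict_to_censoring truncate windows of censored women.
#' @return an object of class `prediction_set`: list with `risks` (matrix,
#'   one column per variant), `window_start`, `window_end`, `id`.
#' @export
predict_cohort <- function(prepared, model, variants = default_variants(),
                           landmark = 1, horizon = 5,
                           predict_to_censoring = FALSE) {
  variants <- .check_variants(variants)
  stopifnot(inherits(model, "hazard_model"), horizon > 0, landmark >= 0)
  df <- as.data.frame(prepared)
  start <- df$baseline_age + landmark
  end <- pmin(start + horizon, model$max_age)
  if (predict_to_censoring) {
    trunc <- df$event == "censored" & df$exit_age < end
    end[trunc] <- pmax(df$exit_age[trunc], start[trunc])
  }
  if (any(start >= end)) stop("prediction window empty for some women; ",
                              "drop pre-landmark exits upstream")
  risks <- vapply(variants, function(v) {
    lam <- .hazard_matrix(df, v, model)
    .window_risk(lam, model$mortality, model$age_breaks, start, end)$risk
  }, numeric(nrow(df)))
  risks <- matrix(risks, nrow = nrow(df),
                  dimnames = list(NULL, names(variants)))
  structure(list(id = df$id, risks = risks, window_start = start,
                 window_end = end, landmark = landmark, horizon = horizon),
            class = "prediction_set")
}

#' @export
as.data.frame.prediction_set <- function(x, ...) {
  nv <- ncol(x$risks)
  data.frame(
    id = rep(x$id, nv),
    variant = rep(colnames(x$risks), each = length(x$id)),
    window_start = rep(x$window_start, nv),
    window_end = rep(x$window_end, nv),
    risk = as.vector(x$risks),
    stringsAsFactors = FALSE
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("prediction_set:", length(x$id), "women x", ncol(x$risks),
      "variants (", paste(colnames(x$risks), collapse = ", "), ")\n")
  cat("  landmark", x$landmark, "y, horizon", x$horizon, "y\n")
  invisible(x)
}
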