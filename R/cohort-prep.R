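#' Derive follow-up under the censoring hierarchy
#'
#' Each woman is followed from baseline to the earliest of: BC diagnosis
#' (invasive or DCIS), bilateral risk-reducing mastectomy, last follow-up,
#' death, baseline plus `landmark + horizon` years, or the administrative
#' maximum age. Ties are resolved in that order, so a BC diagnosis
#' coinciding with another endpoint counts as an event. Under
#' `dcis_policy = "censor"` a DCIS diagnosis censors the woman (unaffected)
#' at the diagnosis age; with `censor_at_rrso = TRUE` risk-reducing
#' salpingo-oophorectomy is an additional censoring endpoint.
#'
#' @param records cohort data frame with `baseline_age`, `bc_age`,
#'   `bc_is_dcis`, `death_age`, `mastectomy_age`, `rrso_age`,
#'   `last_followup_age` (`NA` = absent).
#' @param dcis_policy `"affected"` (DCIS counts as BC) or `"censor"`.
#' @param censor_at_rrso censor at RRSO age.
#' @param landmark,horizon years; the administrative cap is
#'   `baseline + landmark + horizon`.
#' @param max_age administrative maximum age (default 80).
#' @return data frame with `exit_age` and `event` (`"BC"` or `"censored"`).
#' @export
derive_follow_up <- function(records, dcis_policy = c("affected", "censor"),
                             censor_at_rrso = FALSE, landmark = 1, horizon = 5,
                             max_age = 80) {
  dcis_policy <- match.arg(dcis_policy)
  df <- as.data.frame(records)
  inf <- function(x) ifelse(is.na(x), Inf, x)
  bc <- inf(df$bc_age)
  cand <- pmin(bc, inf(df$mastectomy_age), inf(df$last_followup_age),
               inf(df$death_age), df$baseline_age + landmark + horizon,
               max_age)
  if (censor_at_rrso && "rrso_age" %in% names(df)) {
    cand <- pmin(cand, inf(df$rrso_age))
  }
  exit <- cand
  is_dcis <- if ("bc_is_dcis" %in% names(df)) {
    !is.na(df$bc_is_dcis) & df$bc_is_dcis
  } else rep(FALSE, nrow(df))
  event_bc <- bc <= exit & (dcis_policy == "affected" | !is_dcis)
  data.frame(exit_age = exit,
             event = ifelse(event_bc, "BC", "censored"),
             stringsAsFactors = FALSE)
}

#' Apply the cohort eligibility filters
#'
#' Retains women who were younger than 74 at entry, had no history of cancer
#' or bilateral mastectomy before baseline, had more than one year of
#' follow-up, and have complete PRS and questionnaire risk-factor data. The
#' exclusion log records the first failing rule per woman, in that order.
#'
#' @param records cohort data frame.
#' @param exit_age optional pre-derived exit ages (from [derive_follow_up()]);
#'   derived with default settings when missing.
#' @param age_limit upper entry-age limit in years (exclusive).
#' @param min_followup minimum follow-up span in years (exclusive).
#' @return list with `retained` (data frame) and `exclusions`
#'   (data frame `id`, `reason`).
#' @export
apply_eligibility <- function(records, exit_age = NULL, age_limit = 74,
                              min_followup = 1) {
  df <- as.data.frame(records)
  if (is.null(exit_age)) exit_age <- derive_follow_up(df)$exit_age
  prior <- (!is.na(df$bc_age) & df$bc_age <= df$baseline_age) |
    (!is.na(df$mastectomy_age) & df$mastectomy_age <= df$baseline_age)
  qrf_cols <- grep("^qrf_", names(df), value = TRUE)
  missing_data <- is.na(df$prs_z)
  for (cl in qrf_cols) missing_data <- missing_data | is.na(df[[cl]])
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(reason) & df$baseline_age >= age_limit] <- "age"
  reason[is.na(reason) & prior] <- "prior-history"
  reason[is.na(reason) & (exit_age - df$baseline_age) <= min_followup] <- "follow-up"
  reason[is.na(reason) & missing_data] <- "missing-data"
  keep <- is.na(reason)
  list(
    retained = df[keep, , drop = FALSE],
    exclusions = data.frame(id = df$id[!keep], reason = reason[!keep],
                            stringsAsFactors = FALSE)
  )
}

#' Classify the fixed-horizon outcome
#'
#' The binary outcome is `TRUE` iff the woman's follow-up ended in BC inside
#' the landmarked window `(baseline + landmark, baseline + landmark +
#' horizon]`. Women exiting at or before the landmark are dropped with
#' reason `"pre-landmark exit"`. Also computes `time_from_landmark`, the
#' time from the landmark to exit.
#'
#' @param prepared data frame with `baseline_age`, `exit_age`, `event`.
#' @param landmark,horizon years.
#' @return list with `retained` (adds `outcome_5y`, `time_from_landmark`) and
#'   `exclusions`.
#' @export
classify_outcome <- function(prepared, landmark = 1, horizon = 5) {
  df <- as.data.frame(prepared)
  lm_age <- df$baseline_age + landmark
  drop <- df$exit_age <= lm_age
  excl <- data.frame(id = df$id[drop],
                     reason = rep("pre-landmark exit", sum(drop)),
                     stringsAsFactors = FALSE)
  df <- df[!drop, , drop = FALSE]
  lm_age <- df$baseline_age + landmark
  df$outcome_5y <- df$event == "BC" & df$exit_age > lm_age &
    df$exit_age <= lm_age + horizon
  df$time_from_landmark <- df$exit_age - lm_age
  list(retained = df, exclusions = excl)
}

#' Prepare a cohort for validation
#'
#' Applies, in order: the censoring hierarchy ([derive_follow_up()]), the
#' eligibility filters ([apply_eligibility()]) and the landmarked outcome
#' ([classify_outcome()]).
#'
#' @inheritParams derive_follow_up
#' @return an object of class `prepared_cohort`: list with `cohort` (eligible
#'   women with `exit_age`, `event`, `outcome_5y`, `time_from_landmark`) and
#'   `exclusions` (`id`, `reason`).
#' @export
prepare_cohort <- function(records, dcis_policy = c("affected", "censor"),
                           censor_at_rrso = FALSE, landmark = 1, horizon = 5,
                           max_age = 80) {
  dcis_policy <- match.arg(dcis_policy)
  df <- as.data.frame(records)
  fu <- derive_follow_up(df, dcis_policy = dcis_policy,
                         censor_at_rrso = censor_at_rrso,
                         landmark = landmark, horizon = horizon,
                         max_age = max_age)
  elig <- apply_eligibility(df, exit_age = fu$exit_age,
                            min_followup = landmark)
  keep <- df$id %in% elig$retained$id
  work <- cbind(elig$retained, fu[keep, , drop = FALSE])
  cls <- classify_outcome(work, landmark = landmark, horizon = horizon)
  exclusions <- rbind(elig$exclusions, cls$exclusions)
  if (nrow(cls$retained) + nrow(exclusions) != nrow(df)) {
    stop("internal error: retained + excluded != input size")
  }
  structure(list(cohort = cls$retained, exclusions = exclusions,
                 landmark = landmark, horizon = horizon,
                 dcis_policy = dcis_policy, censor_at_rrso = censor_at_rrso),
            class = "prepared_cohort")
}

#' @export
print.prepared_cohort <- function(x, ...) {
  cat("prepared_cohort:", nrow(x$cohort), "eligible women,",
      nrow(x$exclusions), "excluded\n")
  cat("  landmark", x$landmark, "y, horizon", x$horizon,
      "y, DCIS policy:", x$dcis_policy,
      if (x$censor_at_rrso) ", censored at RRSO" else "", "\n")
  cat("  incident BC in window:", sum(x$cohort$outcome_5y), "\n")
  if (nrow(x$exclusions)) {
    tb <- table(x$exclusions$reason)
    cat("  exclusions:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.prepared_cohort <- function(x, ...) x$cohort
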