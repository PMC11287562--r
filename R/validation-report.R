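#' Build a validation report for a prepared cohort
#'
#' Computes, per model variant and per subgroup (all women, then per gene),
#' the weighted calibration and discrimination statistics: E/O ratio,
#' calibration slope, AUC and Harrell's C-index, each with a 95% CI; plus
#' per-variant quintile calibration and, for the last (most complete)
#' variant, the risk-stratification summary.
#'
#' Expected counts (E/O and quintile calibration) are computed on
#' `calibration_predictions`, which should be predicted to the censoring age
#' for women censored inside the window (see [predict_cohort()]) so that
#' expected counts match observable cases. The calibration slope keeps
#' `logit` of the full-horizon `predictions` as its covariate and absorbs
#' each woman's censoring exposure as a fixed offset,
#' `logit(p_truncated) - logit(p_full)`: using the truncated risks as the
#' covariate would bias the slope upward (women censored early are forced
#' to be non-cases at small predictions), while ignoring censoring
#' altogether attenuates it. Discrimination and stratification use
#' `predictions` directly.
#'
#' @param prepared data frame of eligible women (the `cohort` element of a
#'   [prepare_cohort()] result).
#' @param predictions a `prediction_set` from [predict_cohort()].
#' @param calibration_predictions a `prediction_set` for the calibration
#'   statistics; defaults to `predictions`.
#' @param weights positive per-woman weights aligned with `prepared` (or a
#'   data frame from [compute_weights()], matched by `id`); `NULL` for unit
#'   weights.
#' @param thresholds risk-stratification thresholds.
#' @param boot bootstrap replicates for the AUC CI.
#' @param jackknife_groups groups for the Harrell's C jackknife CI.
#' @param by_gene also report per-gene subgroups.
#' @param conf confidence level.
#' @return an object of class `validation_report`: list with `table` (one
#'   row per variant x subgroup), `quintiles` (long data frame), and
#'   `stratification`.
#' @export
validation_report <- function(prepared, predictions,
                              calibration_predictions = predictions,
                              weights = NULL,
                              thresholds = c(0.0165, 0.03, 0.05),
                              boot = 2000, jackknife_groups = 100,
                              by_gene = TRUE, conf = 0.95) {
  df <- as.data.frame(prepared)
  stopifnot(inherits(predictions, "prediction_set"))
  n <- nrow(df)
  if (length(predictions$id) != n || any(predictions$id != df$id)) {
    stop("predictions are not aligned with the prepared cohort")
  }
  if (is.data.frame(weights)) {
    i <- match(df$id, weights$id)
    if (anyNA(i)) stop("weights missing for some women")
    weights <- weights$weight[i]
  }
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))

  variants <- colnames(predictions$risks)
  subgroups <- list(all = rep(TRUE, n))
  if (by_gene) {
    for (g in sort(unique(df$gene))) subgroups[[g]] <- df$gene == g
  }
  y <- df$outcome_5y
  rows <- list()
  quints <- list()
  for (v in variants) {
    p_full <- predictions$risks[, v]
    p_cal <- calibration_predictions$risks[, v]
    for (s in names(subgroups)) {
      i <- subgroups[[s]]
      eo <- expected_observed_ratio(p_cal[i], y[i], weights[i], conf = conf)
      clip2 <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
      cens_off <- stats::qlogis(clip2(p_cal[i])) - stats::qlogis(clip2(p_full[i]))
      sl <- tryCatch(calibration_slope(p_full[i], y[i], weights[i],
                                       conf = conf, offset = cens_off),
                     error = function(e) NULL)
      au <- weighted_auc(p_full[i], y[i], weights[i], boot = boot, conf = conf)
      cc <- harrell_c(p_full[i], df$time_from_landmark[i], df$event[i] == "BC",
                      weights[i], groups = jackknife_groups, conf = conf)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, subgroup = s, n = sum(i),
        O = eo$O, E = eo$E,
        eo = eo$ratio, eo_low = eo$ci[1L], eo_high = eo$ci[2L],
        slope = if (is.null(sl)) NA_real_ else sl$slope,
        slope_low = if (is.null(sl)) NA_real_ else sl$ci[1L],
        slope_high = if (is.null(sl)) NA_real_ else sl$ci[2L],
        auc = au$auc, auc_low = au$ci[1L], auc_high = au$ci[2L],
        c_index = cc$c_index, c_low = cc$ci[1L], c_high = cc$ci[2L],
        stringsAsFactors = FALSE
      )
    }
    q <- quintile_calibration(p_cal, y, weights, conf = conf)
    q <- cbind(variant = v, q, stringsAsFactors = FALSE)
    quints[[v]] <- q
  }
  last <- variants[length(variants)]
  strat <- risk_stratification(predictions$risks[, last], y, weights,
                               thresholds = thresholds,
                               age_at_entry = df$baseline_age,
                               gene = df$gene)
  structure(list(
    table = do.call(rbind, rows),
    quintiles = do.call(rbind, quints),
    stratification = strat,
    stratification_variant = last,
    meta = list(conf = conf, boot = boot,
                jackknife_groups = jackknife_groups,
                eo_ci = "log-normal, SE = sqrt(sum(w^2 y))/O",
                n = n, cases = sum(y))
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  cat("Validation report:", x$meta$n, "women,", x$meta$cases,
      "incident BC in the prediction window\n\n")
  tab <- x$table
  fmt <- function(v, lo, hi) sprintf("%.*f (%.*f-%.*f)", digits, v,
                                     digits, lo, digits, hi)
  show <- data.frame(
    variant = tab$variant, subgroup = tab$subgroup, n = tab$n, O = round(tab$O, 1),
    `E/O` = fmt(tab$eo, tab$eo_low, tab$eo_high),
    slope = fmt(tab$slope, tab$slope_low, tab$slope_high),
    AUC = fmt(tab$auc, tab$auc_low, tab$auc_high),
    `Harrell C` = fmt(tab$c_index, tab$c_low, tab$c_high),
    check.names = FALSE
  )
  print(show, row.names = FALSE)
  st <- x$stratification
  cat("\nRisk stratification (", x$stratification_variant, "):\n", sep = "")
  for (k in seq_len(nrow(st$thresholds))) {
    cat(sprintf("  <%4.2f%%: %5.1f%% of women below, NPV %.3f\n",
                100 * st$thresholds$threshold[k],
                100 * st$thresholds$prop_below[k], st$thresholds$npv[k]))
  }
  cat(sprintf("  top predicted-risk half captures %.1f%% of incident cases\n",
              100 * st$top_half_capture))
  invisible(x)
}

#' Rank model variants by discrimination
#'
#' Orders the all-women rows of a [validation_report()] by Harrell's C-index
#' (highest first) and flags which risk-factor groups each variant uses.
#'
#' @param report a `validation_report` with at least two variants.
#' @param variants optional list of [model_variant()]s used to produce the
#'   report, to recover the factor flags; matched by name.
#' @return data frame ranked by C-index.
#' @export
compare_variants <- function(report, variants = NULL) {
  stopifnot(inherits(report, "validation_report"))
  tab <- report$table[report$table$subgroup == "all", , drop = FALSE]
  if (nrow(tab) < 2L) stop("compare_variants needs at least two variants")
  out <- tab[order(-tab$c_index),
             c("variant", "c_index", "c_low", "c_high", "auc", "eo", "slope")]
  if (!is.null(variants)) {
    variants <- .check_variants(variants)
    flag <- function(field) vapply(out$variant, function(v) {
      if (!is.null(variants[[v]])) variants[[v]][[field]] else NA
    }, logical(1))
    out$uses_gene <- flag("use_gene")
    out$uses_prs <- flag("use_prs")
    out$uses_qrf <- flag("use_qrf")
    out$uses_fh <- flag("use_fh")
  }
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
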