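#' Expected/observed case ratio
#'
#' Overall calibration: `E` is the weighted sum of predicted risks, `O` the
#' weighted count of observed cases, and `E/O` their ratio. The confidence
#' interval is log-normal with a weight-aware Poisson-type standard error
#' `sqrt(sum(w^2 y)) / O` on the log scale.
#'
#' @param pred predicted risks in \[0, 1\].
#' @param outcome binary outcomes (0/1 or logical).
#' @param weights positive weights; `NULL` for unit weights.
#' @param conf confidence level.
#' @return list with `E`, `O`, `ratio`, `ci` (length 2), `se_log`.
#' @export
expected_observed_ratio <- function(pred, outcome, weights = NULL,
                                    conf = 0.95) {
  d <- .check_prob_weights(pred, outcome, weights)
  E <- sum(d$w * d$pred)
  O <- sum(d$w * d$y)
  if (O <= 0) stop("no observed cases: E/O ratio undefined")
  se <- sqrt(sum(d$w^2 * d$y)) / O
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ratio <- E / O
  list(E = E, O = O, ratio = ratio,
       ci = c(ratio * exp(-z * se), ratio * exp(z * se)), se_log = se)
}

#' Calibration slope
#'
#' Weighted logistic regression of the observed outcome on the log odds of
#' the predicted risks. A slope of 1 indicates correctly dispersed risks;
#' below 1, risks are too extreme; above 1, too moderate. Predictions are
#' clipped away from 0 and 1 before the logit. The Wald interval uses a
#' robust (sandwich) standard error, appropriate under sampling weights.
#'
#' With right-censored follow-up, the known per-woman censoring exposure can
#' be supplied as a fixed `offset` on the logit scale (see
#' [validation_report()]): the covariate stays `logit(pred)` and a perfectly
#' calibrated model still has slope 1.
#'
#' @inheritParams expected_observed_ratio
#' @param clip predictions are clipped to `[clip, 1 - clip]`.
#' @param offset optional fixed per-observation offset on the logit scale.
#' @return list with `slope`, `ci`, `se`, `intercept`.
#' @export
calibration_slope <- function(pred, outcome, weights = NULL, conf = 0.95,
                              clip = 1e-6, offset = NULL) {
  d <- .check_prob_weights(pred, outcome, weights)
  if (sum(d$y > 0) == 0 || sum(d$y == 0) == 0) {
    stop("calibration slope needs at least one case and one non-case")
  }
  x <- stats::qlogis(pmin(pmax(d$pred, clip), 1 - clip))
  if (stats::sd(x) == 0) stop("predictions are constant: slope undefined")
  if (is.null(offset)) offset <- rep(0, length(x))
  dat <- data.frame(y = d$y, x = x, w = d$w, off = offset)
  fit <- suppressWarnings(
    stats::glm(y ~ x + offset(off), family = stats::binomial(), data = dat,
               weights = w)
  )
  se <- sqrt(diag(sandwich::vcovHC(fit, type = "HC0")))[["x"]]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  slope <- unname(stats::coef(fit)[["x"]])
  list(slope = slope, ci = c(slope - z * se, slope + z * se), se = se,
       intercept = unname(stats::coef(fit)[["(Intercept)"]]))
}

#' Calibration in quantile bins of predicted risk
#'
#' Bins women at weighted quantiles of the predicted risks (quintiles by
#' default; observations tied at a bin edge go to the lower bin) and reports
#' per-bin expected and observed cases, their ratio and a log-normal CI.
#' Per-bin `E` values sum exactly to the overall `E`.
#'
#' @inheritParams expected_observed_ratio
#' @param n_bins number of bins.
#' @return data frame with one row per bin: `bin`, `lower`, `upper`, `n`,
#'   `E`, `O`, `ratio`, `ci_low`, `ci_high`.
#' @export
quintile_calibration <- function(pred, outcome, weights = NULL, n_bins = 5,
                                 conf = 0.95) {
  d <- .check_prob_weights(pred, outcome, weights)
  if (length(d$pred) < n_bins) stop("fewer observations than bins")
  edges <- weighted_quantile(d$pred, d$w, seq(0, 1, length.out = n_bins + 1L))
  inner <- edges[-c(1L, n_bins + 1L)]
  if (anyDuplicated(inner)) {
    warning("heavy ties in predicted risks: collapsing duplicate bin edges")
  }
  bin <- 1L + rowSums(outer(d$pred, inner, ">"))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    i <- bin == b
    E <- sum(d$w[i] * d$pred[i])
    O <- sum(d$w[i] * d$y[i])
    if (O > 0) {
      se <- sqrt(sum(d$w[i]^2 * d$y[i])) / O
      ci <- (E / O) * exp(c(-1, 1) * z * se)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
               n = sum(i), E = E, O = O,
               ratio = if (O > 0) E / O else NA_real_,
               ci_low = ci[1L], ci_high = ci[2L])
  }))
  rownames(out) <- NULL
  out
}

#' Weighted AUC for a binary outcome
#'
#' The weighted probability that a randomly chosen case has a higher
#' predicted risk than a randomly chosen non-case, ties counted one half
#' (weighted Mann-Whitney form). The CI is a stratified bootstrap
#' (cases and non-cases resampled separately) on the percentile scale.
#'
#' @inheritParams expected_observed_ratio
#' @param ci `"bootstrap"` or `"none"`.
#' @param boot number of bootstrap replicates.
#' @return list with `auc`, `ci`, `n_cases`, `n_controls`.
#' @export
weighted_auc <- function(pred, outcome, weights = NULL,
                         ci = c("bootstrap", "none"), boot = 2000,
                         conf = 0.95) {
  ci <- match.arg(ci)
  d <- .check_prob_weights(pred, outcome, weights)
  case <- d$y > 0
  if (!any(case) || all(case)) stop("AUC needs at least one case and one non-case")
  point <- .auc_stat(d$pred, case, d$w)
  interval <- c(NA_real_, NA_real_)
  if (ci == "bootstrap") {
    i1 <- which(case)
    i0 <- which(!case)
    reps <- vapply(seq_len(boot), function(r) {
      j <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
      .auc_stat(d$pred[j], case[j], d$w[j])
    }, numeric(1))
    a <- (1 - conf) / 2
    interval <- unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE))
  }
  list(auc = point, ci = interval,
       n_cases = sum(case), n_controls = sum(!case))
}

.auc_stat <- function(pred, case, w) {
  uv <- sort(unique(pred))
  idx <- findInterval(pred, uv)
  w0 <- numeric(length(uv))
  t0 <- rowsum(w[!case], idx[!case])
  w0[as.integer(rownames(t0))] <- t0
  cum0 <- cumsum(w0)
  below <- c(0, cum0[-length(cum0)])[idx]
  at <- w0[idx]
  W1 <- sum(w[case])
  W0 <- sum(w[!case])
  if (W1 <= 0 || W0 <= 0) return(NA_real_)
  sum(w[case] * (below[case] + 0.5 * at[case])) / (W1 * W0)
}

#' Harrell's C-index for right-censored data
#'
#' Concordance over comparable pairs: a pair is comparable when the earlier
#' of the two times is an event; it is concordant when that member has the
#' higher predicted risk; prediction ties count one half; pairs with tied
#' times are not comparable. Pair weight is the product of the member
#' weights. The CI is a grouped (delete-a-group) jackknife.
#'
#' @param pred predicted risks (any monotone risk score).
#' @param time follow-up times (> 0), e.g. time from landmark to exit.
#' @param event logical/0-1 event indicators.
#' @param weights positive weights; `NULL` for unit weights.
#' @param ci `"jackknife"` or `"none"`.
#' @param groups number of jackknife groups.
#' @param conf confidence level.
#' @return list with `c_index`, `ci`, `se`, `n_comparable_weight`.
#' @export
harrell_c <- function(pred, time, event, weights = NULL,
                      ci = c("jackknife", "none"), groups = 100,
                      conf = 0.95) {
  ci <- match.arg(ci)
  n <- length(pred)
  stopifnot(length(time) == n, length(event) == n)
  if (any(time <= 0)) stop("times must be positive")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  event <- as.logical(event)
  stat <- function(keep) {
    p <- pred[keep]; tm <- time[keep]; ev <- event[keep]; w <- weights[keep]
    o <- order(-tm)
    r <- findInterval(p, sort(unique(p)))
    cnt <- .concordance_counts(as.integer(r[o]), tm[o], ev[o], w[o],
                               max(r))
    if (cnt[4L] <= 0) return(NA_real_)
    (cnt[1L] + 0.5 * cnt[3L]) / cnt[4L]
  }
  point <- stat(rep(TRUE, n))
  if (is.na(point)) stop("no comparable pairs: C-index undefined")
  se <- NA_real_
  interval <- c(NA_real_, NA_real_)
  if (ci == "jackknife") {
    G <- min(groups, n)
    grp <- rep_len(seq_len(G), n)
    reps <- vapply(seq_len(G), function(g) stat(grp != g), numeric(1))
    reps <- reps[!is.na(reps)]
    G2 <- length(reps)
    if (G2 >= 2) {
      se <- sqrt((G2 - 1) / G2 * sum((reps - mean(reps))^2))
      z <- stats::qnorm(1 - (1 - conf) / 2)
      interval <- c(point - z * se, point + z * se)
    }
  }
  list(c_index = point, ci = interval, se = se,
       n_comparable_weight = NULL)
}

#' Risk stratification at clinical thresholds
#'
#' For each risk threshold: the weighted proportion of women with predicted
#' risk below it and the negative predictive value among them (weighted
#' fraction remaining unaffected). Also reports the breakdown by entry-age
#' group and gene at the highest threshold, and the weighted fraction of
#' incident cases captured by the half of women with the highest predicted
#' risks.
#'
#' @inheritParams expected_observed_ratio
#' @param thresholds strictly increasing risk thresholds in (0, 1).
#' @param age_at_entry optional entry ages for the age-group breakdown.
#' @param gene optional gene labels for the per-gene breakdown.
#' @param age_cutpoints entry-age cutpoints in years.
#' @return list with `thresholds` (data frame: `threshold`, `prop_below`,
#'   `npv`), `subgroups` (proportions below each threshold by age group and
#'   gene, `NULL` when no breakdown variables given) and `top_half_capture`.
#' @export
risk_stratification <- function(pred, outcome, weights = NULL,
                                thresholds = c(0.0165, 0.03, 0.05),
                                age_at_entry = NULL, gene = NULL,
                                age_cutpoints = c(30, 50)) {
  d <- .check_prob_weights(pred, outcome, weights)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must be strictly increasing and in (0, 1)")
  }
  W <- sum(d$w)
  tab <- do.call(rbind, lapply(thresholds, function(th) {
    below <- d$pred < th
    pb <- sum(d$w[below]) / W
    npv <- if (any(below)) {
      1 - sum(d$w[below] * d$y[below]) / sum(d$w[below])
    } else NA_real_
    data.frame(threshold = th, prop_below = pb, npv = npv)
  }))
  subgroups <- NULL
  strata <- list()
  if (!is.null(age_at_entry)) {
    lab <- cut(age_at_entry, c(-Inf, age_cutpoints, Inf),
               labels = c(paste0("<", age_cutpoints[1]),
                          paste0(age_cutpoints[1], "-", age_cutpoints[2]),
                          paste0(">=", age_cutpoints[2])), right = FALSE)
    strata$age_group <- as.character(lab)
  }
  if (!is.null(gene)) strata$gene <- as.character(gene)
  if (length(strata)) {
    subgroups <- do.call(rbind, lapply(names(strata), function(v) {
      do.call(rbind, lapply(unique(strata[[v]]), function(lv) {
        i <- strata[[v]] == lv
        do.call(rbind, lapply(thresholds, function(th) {
          below <- d$pred[i] < th
          data.frame(variable = v, level = lv, threshold = th,
                     prop_below = sum(d$w[i][below]) / sum(d$w[i]),
                     npv = if (any(below)) {
                       1 - sum(d$w[i][below] * d$y[i][below]) /
                         sum(d$w[i][below])
                     } else NA_real_)
        }))
      }))
    }))
    rownames(subgroups) <- NULL
  }
  med <- weighted_quantile(d$pred, d$w, 0.5)
  top <- d$pred > med
  total_cases <- sum(d$w * d$y)
  capture <- if (total_cases > 0) sum(d$w[top] * d$y[top]) / total_cases else NA_real_
  list(thresholds = tab, subgroups = subgroups, top_half_capture = capture)
}
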