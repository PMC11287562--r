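#' Fit the subcohort-inclusion model
#'
#' Per country group, fits a maximum-likelihood logistic regression of the
#' inclusion flag on baseline age, follow-up duration, incident BC status,
#' and the BC-by-age and BC-by-follow-up interactions (six coefficients
#' including the intercept). Countries with fewer women than
#' `min_group_size` are merged into a single pooled group before fitting.
#'
#' @param cohort data frame with `included`, `baseline_age`, `exit_age`,
#'   `event`, `country`.
#' @param grouping optional named vector mapping country -> group label;
#'   defaults to one group per country.
#' @param min_group_size groups smaller than this are pooled.
#' @param floor lower bound for fitted inclusion probabilities when
#'   computing weights (weight cap `1 / floor`).
#' @return an object of class `weight_model`: per-group coefficient vectors,
#'   the country-to-group map and the probability floor.
#' @export
fit_inclusion_model <- function(cohort, grouping = NULL, min_group_size = 200,
                                floor = 0.01) {
  df <- as.data.frame(cohort)
  need <- c("included", "baseline_age", "exit_age", "event", "country")
  if (!all(need %in% names(df))) {
    stop("cohort must have columns: ", paste(need, collapse = ", "))
  }
  if (floor <= 0 || floor >= 1) stop("floor must be in (0, 1)")
  countries <- sort(unique(df$country))
  if (is.null(grouping)) {
    grouping <- stats::setNames(countries, countries)
  }
  if (!all(countries %in% names(grouping))) {
    stop("grouping lacks countries: ",
         paste(setdiff(countries, names(grouping)), collapse = ", "))
  }
  group <- unname(grouping[df$country])
  sizes <- table(group)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small)) {
    grouping[grouping %in% small] <- "pooled"
    group[group %in% small] <- "pooled"
  }
  dat <- data.frame(
    incl = as.numeric(df$included),
    age = df$baseline_age,
    fu = df$exit_age - df$baseline_age,
    bc = as.numeric(df$event == "BC")
  )
  fits <- list()
  for (g in sort(unique(group))) {
    sub <- dat[group == g, , drop = FALSE]
    if (length(unique(sub$incl)) < 2L) {
      stop("inclusion flag is single-class in group '", g,
           "'; cannot fit the inclusion model")
    }
    fit <- withCallingHandlers(
      stats::glm(incl ~ age + fu + bc + bc:age + bc:fu,
                 family = stats::binomial(), data = sub),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          stop("perfect separation in inclusion model for group '", g, "'")
        }
        invokeRestart("muffleWarning")
      }
    )
    fits[[g]] <- stats::coef(fit)
  }
  structure(list(coefficients = fits, grouping = grouping, floor = floor),
            class = "weight_model")
}

# Linear predictor of the inclusion model for a data frame of records.
.inclusion_eta <- function(beta, age, fu, bc) {
  beta[["(Intercept)"]] + beta[["age"]] * age + beta[["fu"]] * fu +
    beta[["bc"]] * bc + beta[["age:bc"]] * age * bc + beta[["fu:bc"]] * fu * bc
}

#' Compute inverse-probability sampling weights
#'
#' Per woman: the fitted inclusion probability from her country group's
#' logistic model, and the weight `1 / max(probability, floor)`.
#'
#' @param model a `weight_model` from [fit_inclusion_model()].
#' @param cohort data frame with `id`, `country`, `baseline_age`,
#'   `exit_age`, `event`.
#' @return data frame `id`, `group`, `probability`, `weight`.
#' @export
compute_weights <- function(model, cohort) {
  stopifnot(inherits(model, "weight_model"))
  df <- as.data.frame(cohort)
  grp <- unname(model$grouping[df$country])
  if (anyNA(grp)) {
    stop("country not mapped to a weighting group: ",
         paste(unique(df$country[is.na(grp)]), collapse = ", "))
  }
  if (!all(grp %in% names(model$coefficients))) {
    stop("no fitted inclusion model for group(s): ",
         paste(setdiff(grp, names(model$coefficients)), collapse = ", "))
  }
  fu <- df$exit_age - df$baseline_age
  bc <- as.numeric(df$event == "BC")
  p <- numeric(nrow(df))
  for (g in unique(grp)) {
    i <- grp == g
    p[i] <- stats::plogis(.inclusion_eta(model$coefficients[[g]],
                                         df$baseline_age[i], fu[i], bc[i]))
  }
  data.frame(id = df$id, group = grp, probability = p,
             weight = 1 / pmax(p, model$floor), stringsAsFactors = FALSE)
}

#' @export
print.weight_model <- function(x, ...) {
  cat("Inclusion (sampling-weight) model:", length(x$coefficients),
      "group(s), probability floor", x$floor, "\n")
  for (g in names(x$coefficients)) {
    cat("  ", g, ": ", paste(sprintf("%s=%.4g", names(x$coefficients[[g]]),
                                     x$coefficients[[g]]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
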