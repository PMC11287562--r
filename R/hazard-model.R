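#' Piecewise-constant multiplicative hazard model
#'
#' Container for an age-banded breast-cancer hazard model. The individual
#' cause-specific BC hazard is multiplicative on the baseline:
#' \deqn{\lambda_i(t) = \lambda_0(t)\, e^{\beta_{gene}(t) + z_i \beta_{PRS}(t)
#'   + \sum_f \beta_{QRF}(f, x_{if}) + n_i \beta_{FH}}}
#' with all components constant within 5-year (or user-chosen) age bands.
#' Competing mortality \eqn{\mu(t)} is banded on the same grid.
#'
#' @param age_breaks strictly increasing band edges in years; bands are
#'   half-open `[a, b)`. The last edge is the model's maximum age.
#' @param bc_incidence baseline BC incidence per year, one value per band.
#' @param mortality competing (non-BC) mortality per year, one value per band.
#' @param log_rr_gene named list (one entry per gene, e.g. `BRCA1`, `BRCA2`)
#'   of per-band log relative hazards.
#' @param log_rr_prs per-band log relative hazard per standard deviation of
#'   the standardized polygenic risk score (age-dependent PRS effect).
#' @param log_rr_qrf named list: questionnaire risk factor -> named vector of
#'   log relative hazards per category. Reference categories must be 0.
#' @param log_rr_fh log relative hazard per affected first-degree relative.
#' @param prs_mean,prs_sd constants used to standardize the raw polygenic
#'   score (defaults from the published 313-SNP score distribution).
#' @return an object of class `hazard_model`.
#' @seealso [default_hazard_model()], [absolute_risk()], [hazard_at_age()]
#' @export
hazard_model <- function(age_breaks, bc_incidence, mortality, log_rr_gene,
                         log_rr_prs, log_rr_qrf = list(), log_rr_fh = 0,
                         prs_mean = -0.424, prs_sd = 0.611) {
  age_breaks <- as.numeric(age_breaks)
  nb <- length(age_breaks) - 1L
  if (nb < 1L || any(diff(age_breaks) <= 0)) {
    stop("age_breaks must be strictly increasing with at least two edges")
  }
  per_band <- function(x, what) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, nb)
    if (length(x) != nb) stop(what, " must have one value per age band")
    x
  }
  bc_incidence <- per_band(bc_incidence, "bc_incidence")
  mortality <- per_band(mortality, "mortality")
  if (any(bc_incidence < 0) || any(mortality < 0)) stop("rates must be >= 0")
  if (!is.list(log_rr_gene) || is.null(names(log_rr_gene))) {
    stop("log_rr_gene must be a named list of per-band vectors")
  }
  log_rr_gene <- lapply(log_rr_gene, per_band, what = "log_rr_gene")
  log_rr_prs <- per_band(log_rr_prs, "log_rr_prs")
  if (!is.list(log_rr_qrf)) stop("log_rr_qrf must be a named list")
  for (f in names(log_rr_qrf)) {
    v <- log_rr_qrf[[f]]
    if (is.null(names(v)) || anyNA(v)) stop("QRF '", f, "' needs named, finite levels")
    if (!any(v == 0)) stop("QRF '", f, "' has no reference category (log RR 0)")
    log_rr_qrf[[f]] <- unlist(v)
  }
  if (!is.numeric(prs_sd) || prs_sd <= 0) stop("prs_sd must be positive")
  structure(list(
    age_breaks = age_breaks,
    bc_incidence = bc_incidence,
    mortality = mortality,
    log_rr_gene = log_rr_gene,
    log_rr_prs = log_rr_prs,
    log_rr_qrf = log_rr_qrf,
    log_rr_fh = as.numeric(log_rr_fh),
    prs_mean = as.numeric(prs_mean),
    prs_sd = as.numeric(prs_sd),
    max_age = age_breaks[length(age_breaks)]
  ), class = "hazard_model")
}

#' Default carrier hazard model
#'
#' An illustrative BRCA1/2 carrier model on 5-year bands from age 20 to 80:
#' population-scale baseline incidence and mortality, large age-declining
#' gene relative hazards (earlier onset for BRCA1 than BRCA2, cumulative risk
#' to age 80 of roughly 70% for both genes), an age-declining PRS effect of
#' about 1.25-1.65 per SD, three questionnaire risk factors and a family
#' history effect of 1.8 per affected first-degree relative. Used as the
#' synthetic-cohort generator truth and as the default predictor.
#'
#' @return a `hazard_model`.
#' @export
default_hazard_model <- function() {
  hazard_model(
    age_breaks = seq(20, 80, by = 5),
    bc_incidence = c(0.00006, 0.00025, 0.0006, 0.0011, 0.0017, 0.0023,
                     0.0027, 0.0030, 0.0033, 0.0035, 0.0037, 0.0039),
    mortality = c(0.0004, 0.0004, 0.0005, 0.0007, 0.0010, 0.0016,
                  0.0026, 0.0042, 0.0066, 0.0105, 0.0170, 0.0280),
    log_rr_gene = list(
      BRCA1 = log(c(40, 40, 35, 28, 20, 14, 10, 8, 6.5, 5.5, 4.5, 4)),
      BRCA2 = log(c(10, 12, 13, 14, 14, 12.5, 11, 10, 9, 8, 7, 6))
    ),
    log_rr_prs = log(c(1.65, 1.60, 1.55, 1.50, 1.45, 1.42,
                       1.38, 1.35, 1.32, 1.30, 1.28, 1.25)),
    log_rr_qrf = list(
      parity = c(nulliparous = 0, parous = log(0.92)),
      mht = c(never = 0, past = log(1.05), current = log(1.30)),
      bmi = c(normal = 0, overweight = log(1.10), obese = log(1.15))
    ),
    log_rr_fh = log(1.8)
  )
}

.n_bands <- function(model) length(model$age_breaks) - 1L

# Band index for ages in [first edge, max_age); errors outside.
.band_index <- function(age, model) {
  br <- model$age_breaks
  if (any(age < br[1L] | age >= model$max_age)) {
    stop("age outside the model's age grid [", br[1L], ", ", model$max_age, ")")
  }
  findInterval(age, br)
}

# n x n_bands matrix of log relative hazards for a cohort data frame under a
# model variant. QRF and FH contributions are age-constant; gene and PRS
# contributions are per band.
.log_rr_matrix <- function(df, variant, model) {
  n <- nrow(df)
  nb <- .n_bands(model)
  lp <- matrix(0, n, nb)
  if (variant$use_gene) {
    genes <- names(model$log_rr_gene)
    idx <- match(as.character(df$gene), genes)
    if (anyNA(idx)) stop("unknown gene label in cohort: ",
                         paste(unique(df$gene[is.na(idx)]), collapse = ", "))
    G <- do.call(rbind, model$log_rr_gene)
    lp <- lp + G[idx, , drop = FALSE]
  }
  if (variant$use_prs) {
    lp <- lp + outer(as.numeric(df$prs_z), model$log_rr_prs)
  }
  scalar <- numeric(n)
  if (variant$use_qrf) {
    for (f in names(model$log_rr_qrf)) {
      col <- paste0("qrf_", f)
      if (!col %in% names(df)) stop("cohort lacks QRF column '", col, "'")
      v <- model$log_rr_qrf[[f]][as.character(df[[col]])]
      if (anyNA(v)) stop("unknown category for QRF '", f, "'")
      scalar <- scalar + unname(v)
    }
  }
  if (variant$use_fh) scalar <- scalar + as.numeric(df$fh_score) * model$log_rr_fh
  lp + scalar
}

#' Read or write a hazard model as JSON
#'
#' @param model a `hazard_model`.
#' @param path file path.
#' @return `read_hazard_model` returns a `hazard_model`;
#'   `write_hazard_model` returns `path` invisibly.
#' @export
write_hazard_model <- function(model, path) {
  stopifnot(inherits(model, "hazard_model"))
  x <- unclass(model)
  x$max_age <- NULL
  # named vectors must serialize as JSON objects, not bare arrays
  x$log_rr_qrf <- lapply(x$log_rr_qrf, as.list)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hazard_model
#' @export
read_hazard_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  qrf <- lapply(x$log_rr_qrf, unlist)
  hazard_model(
    age_breaks = x$age_breaks, bc_incidence = x$bc_incidence,
    mortality = x$mortality, log_rr_gene = as.list(x$log_rr_gene),
    log_rr_prs = x$log_rr_prs, log_rr_qrf = qrf, log_rr_fh = x$log_rr_fh,
    prs_mean = x$prs_mean, prs_sd = x$prs_sd
  )
}

#' @export
print.hazard_model <- function(x, ...) {
  cat("Piecewise-constant multiplicative hazard model\n")
  cat("  age grid:", x$age_breaks[1L], "-", x$max_age, "years,",
      .n_bands(x), "bands\n")
  cat("  genes:", paste(names(x$log_rr_gene), collapse = ", "), "\n")
  cat("  QRFs:", if (length(x$log_rr_qrf)) paste(names(x$log_rr_qrf), collapse = ", ") else "none", "\n")
  cat("  FH log RR per affected relative:", format(x$log_rr_fh), "\n")
  cat("  PRS standardization: mean", x$prs_mean, ", SD", x$prs_sd, "\n")
  invisible(x)
}
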