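#' Configuration for an end-to-end validation run
#'
#' Bundles the inputs and options of the full pipeline: a cohort (in-memory
#' data frame, CSV path, or a [simulation_config()] to generate one), the
#' predictor [hazard_model()], the variant list, landmark/horizon, censoring
#' policies, weighting options and interval-estimation sizes.
#'
#' @param cohort cohort data frame, or `NULL`.
#' @param cohort_csv path to a cohort CSV (ignored when `cohort` is given).
#' @param sim_config a [simulation_config()] used when no cohort is supplied.
#' @param model predictor [hazard_model()] or path to its JSON file.
#' @param variants list of [model_variant()]s.
#' @param landmark,horizon prediction window in years.
#' @param dcis_policy `"affected"` or `"censor"`.
#' @param censor_at_rrso censor follow-up at RRSO.
#' @param auc_predict_to_censoring use censoring-truncated predictions for
#'   the discrimination metrics as well (the calibration metrics always use
#'   them).
#' @param weighting `"auto"` (weight when any woman is not included),
#'   `"on"` or `"off"`.
#' @param min_group_size,floor see [fit_inclusion_model()].
#' @param thresholds risk-stratification thresholds.
#' @param boot,jackknife_groups interval-estimation sizes.
#' @param seed integer seed for all run randomness (bootstrap resampling).
#' @param out_dir optional output directory for report files.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, cohort_csv = NULL, sim_config = NULL,
                       model = default_hazard_model(),
                       variants = default_variants(),
                       landmark = 1, horizon = 5,
                       dcis_policy = c("affected", "censor"),
                       censor_at_rrso = FALSE,
                       auc_predict_to_censoring = FALSE,
                       weighting = c("auto", "on", "off"),
                       min_group_size = 200, floor = 0.01,
                       thresholds = c(0.0165, 0.03, 0.05),
                       boot = 2000, jackknife_groups = 100,
                       seed = 1L, out_dir = NULL) {
  dcis_policy <- match.arg(dcis_policy)
  weighting <- match.arg(weighting)
  if (is.character(model)) model <- read_hazard_model(model)
  stopifnot(inherits(model, "hazard_model"), horizon > 0, landmark >= 0)
  if (is.null(cohort) && is.null(cohort_csv) && is.null(sim_config)) {
    stop("supply a cohort, a cohort_csv path or a sim_config")
  }
  structure(list(cohort = cohort, cohort_csv = cohort_csv,
                 sim_config = sim_config, model = model,
                 variants = .check_variants(variants),
                 landmark = landmark, horizon = horizon,
                 dcis_policy = dcis_policy, censor_at_rrso = censor_at_rrso,
                 auc_predict_to_censoring = auc_predict_to_censoring,
                 weighting = weighting, min_group_size = min_group_size,
                 floor = floor, thresholds = thresholds, boot = boot,
                 jackknife_groups = jackknife_groups,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full validation pipeline
#'
#' Orchestrates simulate/load, prepare, weight, predict and validate as one
#' seeded, logged run. With an output directory set, writes the report as
#' CSV and JSON, the per-quintile calibration table, the exclusion log, the
#' weights file and a run manifest. Identical configuration and seed give
#' identical outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with `report` ([validation_report()]),
#'   `prepared`, `weights`, `predictions`, `calibration_predictions`,
#'   `cohort` and `files` (paths written, if any).
#' @export
run_validation <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[bcriskval] ", ...)

  cohort <- config$cohort
  if (is.null(cohort) && !is.null(config$cohort_csv)) {
    say("reading cohort from ", config$cohort_csv)
    cohort <- read_cohort_csv(config$cohort_csv)
  }
  if (is.null(cohort)) {
    say("simulating cohort: n = ", config$sim_config$n_women,
        ", seed = ", config$sim_config$seed)
    cohort <- simulate_cohort(config$sim_config)
  }
  say("cohort: ", nrow(cohort), " women")

  prep <- prepare_cohort(cohort, dcis_policy = config$dcis_policy,
                         censor_at_rrso = config$censor_at_rrso,
                         landmark = config$landmark, horizon = config$horizon,
                         max_age = config$model$max_age)
  say("eligible after censoring/eligibility: ", nrow(prep$cohort),
      " (excluded ", nrow(prep$exclusions), ")")

  analysis <- prep$cohort
  weights_df <- NULL
  w <- NULL
  use_w <- config$weighting == "on" ||
    (config$weighting == "auto" && "included" %in% names(analysis) &&
       !all(analysis$included))
  if (use_w) {
    wm <- fit_inclusion_model(analysis, min_group_size = config$min_group_size,
                              floor = config$floor)
    weights_df <- compute_weights(wm, analysis)
    keep <- analysis$included
    analysis <- analysis[keep, , drop = FALSE]
    weights_df <- weights_df[keep, , drop = FALSE]
    w <- weights_df$weight
    say("weighting on: ", nrow(analysis), " included women, ",
        "weight sum ", round(sum(w), 1))
  } else {
    say("weighting off: unit weights")
  }

  say("predicting ", length(config$variants), " variants")
  pred_full <- predict_cohort(analysis, config$model, config$variants,
                              landmark = config$landmark,
                              horizon = config$horizon,
                              predict_to_censoring = config$auc_predict_to_censoring)
  pred_cal <- predict_cohort(analysis, config$model, config$variants,
                             landmark = config$landmark,
                             horizon = config$horizon,
                             predict_to_censoring = TRUE)

  set.seed(config$seed)
  report <- validation_report(analysis, pred_full,
                              calibration_predictions = pred_cal,
                              weights = w, thresholds = config$thresholds,
                              boot = config$boot,
                              jackknife_groups = config$jackknife_groups)
  say("validated: ", report$meta$cases, " incident cases among ",
      report$meta$n, " women")

  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(config$out_dir, x)
    utils::write.csv(report$table, fp("report.csv"), row.names = FALSE)
    utils::write.csv(report$quintiles, fp("quintiles.csv"), row.names = FALSE)
    utils::write.csv(prep$exclusions, fp("exclusions.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(table = report$table, quintiles = report$quintiles,
           stratification = report$stratification, meta = report$meta),
      fp("report.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(weights_df)) {
      utils::write.csv(weights_df, fp("weights.csv"), row.names = FALSE)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("bcriskval")),
      r_version = R.version.string,
      seed = config$seed,
      landmark = config$landmark, horizon = config$horizon,
      dcis_policy = config$dcis_policy, censor_at_rrso = config$censor_at_rrso,
      weighting = config$weighting, boot = config$boot,
      variants = names(config$variants),
      n_input = nrow(cohort), n_eligible = nrow(prep$cohort),
      n_analysis = report$meta$n, cases = report$meta$cases
    )
    jsonlite::write_json(manifest, fp("manifest.json"), digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
    files <- vapply(c("report.csv", "quintiles.csv", "exclusions.csv",
                      "report.json", "manifest.json"), fp, character(1))
    say("wrote outputs to ", config$out_dir)
  }
  invisible(list(report = report, prepared = prep, weights = weights_df,
                 predictions = pred_full, calibration_predictions = pred_cal,
                 cohort = cohort, files = files))
}
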