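# End-to-end workflow: file-based training and blinded validation runs.
# Every output file is stamped with the md5 of the run configuration and
# the seed, so two runs with equal stamps are identical.

#' Build a workflow run configuration
#'
#' Collects the file paths, thresholds and flags the [run_train()] /
#' [run_validate()] stages consume. Either `plates` (raw plate CSV) or
#' `auc` (precomputed sensitivity-profile CSV) must be given for training.
#'
#' @param expression path to the cell-line log2 expression TSV.
#' @param plates path to a plate CSV ([load_plates()]); used when `auc` is
#'   NULL.
#' @param auc path to a sensitivity-profile CSV (`cell_line_id`, `auc`).
#' @param patient_expression path to the patient log2 expression TSV.
#' @param clinical path to the clinical cohort CSV.
#' @param out_dir directory for all outputs (created if needed).
#' @param threshold fixed feature-score threshold; NULL selects by CV.
#' @param candidate_thresholds optional CV grid.
#' @param iqr_min,median_min probe-filter thresholds.
#' @param k CV folds.
#' @param alpha two-sided error rate for intervals.
#' @param n_perm permutations for enrichment runs.
#' @param seed integer seed recorded in every output.
#' @param positive_low TRUE if lower scores predict response.
#' @param universe patient standardization universe, `"training"` or
#'   `"model"` (see [predict.mgp()]).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(expression = NULL, plates = NULL, auc = NULL,
                       patient_expression = NULL, clinical = NULL,
                       out_dir = ".", threshold = NULL,
                       candidate_thresholds = NULL, iqr_min = 0.5,
                       median_min = log2(100), k = 10, alpha = 0.05,
                       n_perm = 1000, seed = 1, positive_low = TRUE,
                       universe = "training") {
  structure(list(expression = expression, plates = plates, auc = auc,
                 patient_expression = patient_expression,
                 clinical = clinical, out_dir = out_dir,
                 threshold = threshold,
                 candidate_thresholds = candidate_thresholds,
                 iqr_min = iqr_min, median_min = median_min, k = k,
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 positive_low = positive_low, universe = universe),
            class = "run_config")
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Train a predictor from files
#'
#' Reads the dose-response input (raw plates or a precomputed sensitivity
#' profile) and the cell-line expression matrix, runs [mgp_fit()] (with a
#' fixed threshold when `config$threshold` is set, skipping
#' cross-validation), and writes `model.json`, `filter_report.csv`,
#' `screening.csv` and, when cross-validation ran, `cv_curve.csv` under
#' `config$out_dir`. Stage counts (probes in, after filtering, selected)
#' are logged via `message()`.
#'
#' @param config a [run_config()].
#' @return The fitted `"mgp"` model, invisibly.
#' @export
run_train <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$expression))
    stopf("run_train: config$expression is required")
  hash <- config_hash(unclass(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  y <- if (!is.null(config$auc)) {
    message("run_train: reading sensitivity profile from ", config$auc)
    read_sensitivity_profile(config$auc)
  } else if (!is.null(config$plates)) {
    message("run_train: computing AUC scores from plates in ", config$plates)
    sensitivity_profile(load_plates(config$plates))
  } else stopf("run_train: either config$plates or config$auc is required")

  x <- load_expression_matrix(config$expression)
  message(sprintf("run_train: %d probes x %d samples in", nrow(x), ncol(x)))
  if (!is.null(config$threshold))
    message(sprintf(
      "run_train: fixed threshold %.4g supplied; cross-validation skipped",
      config$threshold))
  model <- mgp_fit(x, y, threshold = config$threshold,
                   candidate_thresholds = config$candidate_thresholds,
                   k = config$k, seed = config$seed,
                   iqr_min = config$iqr_min, median_min = config$median_min)
  rep <- model$preprocessing$filter_report
  message(sprintf("run_train: %d probes kept after filtering, %d selected",
                  length(rep$kept_probes), length(model$selected_probe_ids)))

  write_mgp(model, file.path(config$out_dir, "model.json"),
            extra = list(config_hash = hash))
  write_stamped_csv(
    data.frame(probe_id = c(rep$kept_probes, rep$dropped_low_variation,
                            rep$dropped_low_expression),
               status = rep(c("kept", "dropped_low_variation",
                              "dropped_low_expression"),
                            c(length(rep$kept_probes),
                              length(rep$dropped_low_variation),
                              length(rep$dropped_low_expression)))),
    file.path(config$out_dir, "filter_report.csv"), hash, config$seed)
  scr <- model$screen
  scr$score <- format_full(scr$score)
  scr$p_value <- format_full(scr$p_value)
  scr$q_value <- format_full(scr$q_value)
  write_stamped_csv(scr, file.path(config$out_dir, "screening.csv"),
                    hash, config$seed)
  if (!is.null(model$cv))
    write_stamped_csv(
      data.frame(threshold = format_full(model$cv$curve$threshold),
                 mean_stat = format_full(model$cv$curve$mean_stat),
                 se_stat = format_full(model$cv$curve$se_stat)),
      file.path(config$out_dir, "cv_curve.csv"), hash, config$seed)
  invisible(model)
}

#' Score and validate a patient cohort from files
#'
#' Scores the patient expression matrix with the model and writes
#' `scores.csv` *before* the clinical table is read, preserving the
#' blinding of genomic predictions to outcome. Then reads the clinical
#' table, runs [validate_cohort()] (per-arm and per-ER-subgroup ROC
#' analyses, Wilcoxon comparisons, univariate and multivariate logistic
#' odds-ratio tables) and writes `validation.json` and `validation.txt`.
#'
#' @param config a [run_config()] with `patient_expression` and `clinical`.
#' @param model an `"mgp"` fit or a path to a serialized `model.json`.
#' @return The `"mgp_validation"` report, invisibly.
#' @export
run_validate <- function(config, model) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(model)) model <- read_mgp(model)
  stopifnot(inherits(model, "mgp"))
  if (is.null(config$patient_expression) || is.null(config$clinical))
    stopf("run_validate: patient_expression and clinical paths are required")
  hash <- config_hash(unclass(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1 (blinded): scores are computed and persisted before any
  # clinical information is touched
  xp <- load_expression_matrix(config$patient_expression)
  scores <- predict(model, xp, universe = config$universe)
  write_stamped_csv(data.frame(sample_id = names(scores),
                               score = format_full(unname(scores))),
                    file.path(config$out_dir, "scores.csv"),
                    hash, config$seed)

  # stage 2: unblind and validate
  cohort <- load_clinical_table(config$clinical)
  report <- validate_cohort(scores, cohort, alpha = config$alpha,
                            positive_low = config$positive_low)

  json <- list(config_hash = hash, seed = config$seed,
               subgroups = lapply(report$subgroups, function(s)
                 list(n = s$n, n_pcr = s$n_pcr, mean_pcr = s$mean_pcr,
                      mean_rd = s$mean_rd, wilcoxon_p = s$wilcoxon_p,
                      auc = s$roc$auc, ci_low = s$roc$ci_low,
                      ci_high = s$roc$ci_high,
                      degenerate = s$roc$degenerate)),
               logistic = report$logistic)
  jsonlite::write_json(json, file.path(config$out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  txt <- c(sprintf("# config_hash=%s seed=%d", hash, config$seed),
           utils::capture.output(print(report)))
  writeLines(txt, file.path(config$out_dir, "validation.txt"))
  invisible(report)
}
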