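# Synthetic-data generators: a cell-line panel whose dose-response AUC is
# linearly driven by a latent sensitivity expressed in a planted probe
# subset, and a patient cohort whose binary pCR outcome follows a logistic
# function of the same latent sensitivity. Every generator is a pure
# function of (config, seed).

#' Configuration for a synthetic cell-line panel
#'
#' Defaults emulate the study conditions the package targets: a panel of 42
#' cell lines, 2000 probes of which 50 carry signal, homoscedastic normal
#' noise on the log2 scale, and AUC sensitivity scores centered at 5 with
#' spread 1.5. Informative probes sit well above the median-expression
#' filter threshold; uninformative baselines straddle it so that filtering
#' has real work to do.
#'
#' @param n_cell_lines panel size.
#' @param n_probes total probes.
#' @param n_informative probes carrying the latent sensitivity signal.
#' @param effect_beta log2 expression change per latent-sensitivity unit.
#' @param noise_sd residual sd of probe expression (log2 units).
#' @param auc_mean,auc_sd center and spread of the AUC scores.
#' @param auc_noise_sd sd of the measurement noise added to AUC on top of
#'   the latent signal.
#' @param baseline_mean,baseline_sd distribution of informative-probe
#'   baselines (log2 units).
#' @param null_baseline_mean,null_baseline_sd distribution of uninformative
#'   baselines; the default centers on the median-filter threshold
#'   log2(100).
#' @param seed integer seed.
#' @return List of class `"panel_config"`.
#' @export
panel_config <- function(n_cell_lines = 42, n_probes = 2000,
                         n_informative = 50, effect_beta = 1.0,
                         noise_sd = 0.5, auc_mean = 5.0, auc_sd = 1.5,
                         auc_noise_sd = 0.2, baseline_mean = 8.0,
                         baseline_sd = 0.5, null_baseline_mean = log2(100),
                         null_baseline_sd = 1.0, seed = 1) {
  cfg <- list(n_cell_lines = n_cell_lines, n_probes = n_probes,
              n_informative = n_informative, effect_beta = effect_beta,
              noise_sd = noise_sd, auc_mean = auc_mean, auc_sd = auc_sd,
              auc_noise_sd = auc_noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              null_baseline_mean = null_baseline_mean,
              null_baseline_sd = null_baseline_sd, seed = seed)
  if (cfg$n_informative > cfg$n_probes)
    stopf("n_informative must not exceed n_probes")
  if (cfg$noise_sd <= 0 || cfg$auc_sd <= 0) stopf("sds must be > 0")
  structure(cfg, class = "panel_config")
}

#' Generate a synthetic cell-line panel with planted signal probes
#'
#' Each cell line i gets a latent sensitivity u_i ~ N(0, 1). Its AUC score
#' is `auc_mean + auc_sd * u_i` plus small measurement noise, truncated at
#' zero. Each informative probe j has expression `baseline_j + effect_beta
#' * u_i + noise`; uninformative probes are independent noise around
#' baselines drawn to straddle the median-filter threshold. The planted
#' probe ids are returned as ground truth, at seeded random positions in
#' the matrix.
#'
#' @param cfg a [panel_config()].
#' @return List with `expression` (probes x samples log2 matrix,
#'   unfiltered/unstandardized), `auc` (named sensitivity profile),
#'   `planted` (informative probe ids), `latent` (the u vector), and
#'   `truth` (generative parameters reused by
#'   [generate_patient_cohort()]).
#' @export
generate_cell_line_panel <- function(cfg = panel_config()) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cell_lines
    p <- cfg$n_probes
    samples <- sprintf("CL%03d", seq_len(n))
    probes <- sprintf("P%05d", seq_len(p))
    u <- stats::rnorm(n)
    auc <- pmax(0, cfg$auc_mean + cfg$auc_sd * u +
                  stats::rnorm(n, 0, cfg$auc_noise_sd))
    names(auc) <- samples
    planted <- sort(sample(probes, cfg$n_informative))
    baselines <- stats::setNames(
      stats::rnorm(p, cfg$null_baseline_mean, cfg$null_baseline_sd), probes)
    baselines[planted] <- stats::rnorm(cfg$n_informative, cfg$baseline_mean,
                                       cfg$baseline_sd)
    x <- matrix(stats::rnorm(p * n, 0, cfg$noise_sd), p, n,
                dimnames = list(probes, samples))
    x <- x + baselines
    x[planted, ] <- x[planted, ] +
      cfg$effect_beta * matrix(u, cfg$n_informative, n, byrow = TRUE)
    list(expression = x, auc = auc, planted = planted,
         latent = stats::setNames(u, samples),
         truth = list(baselines = baselines, planted = planted,
                      effect_beta = cfg$effect_beta,
                      noise_sd = cfg$noise_sd, config = cfg))
  })
}

#' Generate a dose-response plate targeting a given AUC
#'
#' Builds a monotone nonincreasing logistic kill curve whose ten survival
#' fractions sum to `target_auc` (bisection on the curve midpoint), then
#' draws integer well counts with multiplicative lognormal noise around
#' `sf * control_mean`. With the default noise level the recovered AUC is
#' within 0.3 of the target with probability at least 0.95.
#'
#' @param cell_line_id identifier for the plate.
#' @param target_auc desired AUC in [0, 10].
#' @param seed integer seed.
#' @param n_replicates treated wells per dose (default 3).
#' @param n_controls control wells (default 16, a full control column on a
#'   384-well plate; the control mean dominates the AUC error budget, so
#'   plates carry many more control than treated replicates).
#' @param control_mean expected control-well cell count.
#' @param noise_cv coefficient of variation of the multiplicative well
#'   noise.
#' @param curve_slope logistic steepness (doses per e-fold of kill).
#' @return A [dr_plate()].
#' @export
generate_dose_response_plate <- function(cell_line_id, target_auc, seed = 1,
                                         n_replicates = 3, n_controls = 16,
                                         control_mean = 1000,
                                         noise_cv = 0.05,
                                         curve_slope = 1.5) {
  if (!is.finite(target_auc) || target_auc < 0 || target_auc > 10)
    stopf("target_auc must lie in [0, 10], got %s", format(target_auc))
  doses <- 1:10
  sf_of <- function(m) stats::plogis((m - doses) / curve_slope)
  if (target_auc <= 1e-9) {
    sf <- rep(0, 10)
  } else if (target_auc >= 10 - 1e-9) {
    sf <- rep(1, 10)
  } else {
    lo <- -80; hi <- 90
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (sum(sf_of(mid)) < target_auc) lo <- mid else hi <- mid
    }
    sf <- sf_of((lo + hi) / 2)
  }
  with_seed(seed, {
    treated <- data.frame(
      dose_index = rep(doses, each = n_replicates),
      well_id = paste0("w", seq_len(10 * n_replicates)),
      count = round(rep(sf, each = n_replicates) * control_mean *
                      exp(stats::rnorm(10 * n_replicates, 0, noise_cv))))
    control <- round(control_mean * exp(stats::rnorm(n_controls, 0, noise_cv)))
    dr_plate(cell_line_id, treated, control)
  })
}

#' Configuration for a synthetic patient cohort
#'
#' Defaults emulate a neoadjuvant trial cohort: 66 patients, a pathologic
#' complete response (pCR) probability following a logistic function of the
#' latent sensitivity with negative slope (lower sensitivity score = higher
#' pCR odds; the defaults give a mean pCR fraction near 0.4), and a patient
#' platform carrying a random 90% of the panel's probes. Clinical
#' covariates are drawn from categorical distributions resembling such a
#' trial, independently of the latent sensitivity, so only the expression
#' score carries outcome signal.
#'
#' @param n_patients cohort size.
#' @param pcr_intercept,pcr_slope logistic coefficients of
#'   P(pCR) = plogis(intercept + slope * u); slope should be negative.
#' @param platform_probe_fraction fraction of panel probes present on the
#'   patient platform, in (0, 1].
#' @param covariates named list of category probability vectors for `arm`,
#'   `er`, `pr`, `nodal`, `grade`, `t_stage`, plus `age_range`.
#' @param seed integer seed.
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 66, pcr_intercept = -0.7,
                          pcr_slope = -2.5, platform_probe_fraction = 0.9,
                          covariates = NULL, seed = 1) {
  default_cov <- list(
    arm = c("FEC/TX" = 0.725, "FEC/TX+H" = 0.275),
    er = c(positive = 0.43, negative = 0.54, unknown = 0.03),
    pr = c(positive = 0.40, negative = 0.55, unknown = 0.05),
    nodal = c(N0 = 0.33, N1 = 0.50, N2 = 0.09, N3 = 0.06, unknown = 0.02),
    grade = c("1&2" = 0.25, "3" = 0.60, unknown = 0.15),
    t_stage = c(T1 = 0.02, T2 = 0.37, T3 = 0.50, T4 = 0.11),
    age_range = c(26, 69))
  if (!is.null(covariates)) default_cov[names(covariates)] <- covariates
  cfg <- list(n_patients = n_patients, pcr_intercept = pcr_intercept,
              pcr_slope = pcr_slope,
              platform_probe_fraction = platform_probe_fraction,
              covariates = default_cov, seed = seed)
  if (cfg$n_patients < 2) stopf("n_patients must be >= 2")
  if (cfg$platform_probe_fraction <= 0 || cfg$platform_probe_fraction > 1)
    stopf("platform_probe_fraction must lie in (0, 1]")
  for (nm in setdiff(names(default_cov), "age_range"))
    if (any(default_cov[[nm]] < 0) || abs(sum(default_cov[[nm]]) - 1) > 1e-6)
      stopf("covariate probabilities for '%s' must be nonnegative and sum to 1", nm)
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic patient cohort tied to a panel's generative truth
#'
#' Patients receive fresh latent sensitivities u ~ N(0, 1); their
#' expression follows the same generative law as the panel (same planted
#' probes, baselines, effect size and noise), restricted to a seeded random
#' `platform_probe_fraction` of the probes. The pCR outcome is Bernoulli
#' with probability `plogis(pcr_intercept + pcr_slope * u)`; clinical
#' covariates are drawn independently of u. A degenerate outcome vector
#' (all pCR or all RD) is redrawn up to 10 times with a warning.
#'
#' @param cfg a [cohort_config()].
#' @param panel_truth the `truth` element returned by
#'   [generate_cell_line_panel()].
#' @return List with `expression` (platform-restricted probes x patients),
#'   `cohort` (clinical data.frame), `latent` (named u vector).
#' @export
generate_patient_cohort <- function(cfg = cohort_config(), panel_truth) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.null(panel_truth$baselines) || is.null(panel_truth$planted))
    stopf("panel_truth must carry baselines and planted probe ids")
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    ids <- sprintf("PT%03d", seq_len(n))
    probes_all <- names(panel_truth$baselines)
    keep <- sort(sample(probes_all,
                        round(cfg$platform_probe_fraction *
                                length(probes_all))))
    u <- stats::setNames(stats::rnorm(n), ids)
    x <- matrix(stats::rnorm(length(keep) * n, 0, panel_truth$noise_sd),
                length(keep), n, dimnames = list(keep, ids))
    x <- x + panel_truth$baselines[keep]
    planted_kept <- intersect(panel_truth$planted, keep)
    x[planted_kept, ] <- x[planted_kept, ] +
      panel_truth$effect_beta * matrix(u, length(planted_kept), n,
                                       byrow = TRUE)
    prob <- stats::plogis(cfg$pcr_intercept + cfg$pcr_slope * u)
    response <- NULL
    for (attempt in 1:10) {
      y <- stats::rbinom(n, 1, prob)
      if (length(unique(y)) == 2L) { response <- y; break }
      warnf("degenerate outcome draw (attempt %d); redrawing", attempt)
    }
    if (is.null(response))
      stopf("could not draw a non-degenerate outcome in 10 attempts")

    cv <- cfg$covariates
    draw <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
    arm <- draw(cv$arm, n)
    her2 <- ifelse(arm == "FEC/TX+H",
                   ifelse(stats::runif(n) < 0.95, "positive", "negative"),
                   ifelse(stats::runif(n) < 0.15, "positive", "negative"))
    cohort <- data.frame(
      sample_id = ids,
      response = ifelse(response == 1, "pCR", "RD"),
      arm = arm,
      er = draw(cv$er, n), pr = draw(cv$pr, n), her2 = her2,
      nodal = draw(cv$nodal, n), grade = draw(cv$grade, n),
      t_stage = draw(cv$t_stage, n),
      age = sample(seq(cv$age_range[1], cv$age_range[2]), n, replace = TRUE),
      stringsAsFactors = FALSE)
    list(expression = x, cohort = cohort, latent = u)
  })
}

#' Read / write a clinical cohort table
#'
#' CSV with the cohort columns (`sample_id`, `response`, `arm`, `er`, `pr`,
#' `her2`, `nodal`, `grade`, `t_stage`, `age`); the literal `unknown` marks
#' missing categorical values. `response` and `arm` may never be unknown.
#'
#' @param cohort clinical data.frame.
#' @param path file path.
#' @export
write_clinical_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
load_clinical_table <- function(path) {
  if (!file.exists(path)) stopf("clinical table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "response", "arm")
  if (!all(required %in% names(df)))
    stopf("%s: missing columns %s", path,
          paste(setdiff(required, names(df)), collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stopf("%s: duplicate sample id(s)", path)
  if (!all(df$response %in% c("pCR", "RD")))
    stopf("%s: response must be pCR or RD for every patient", path)
  if (any(df$arm == "unknown"))
    stopf("%s: arm may not be unknown", path)
  df
}
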