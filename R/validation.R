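#' Rank-based ROC area (Mann-Whitney statistic)
#'
#' The AU-ROC is the fraction of (positive, negative) pairs ordered
#' correctly, counting ties as 1/2. With `positive_low = TRUE` (the default,
#' matching a sensitivity score where lower means more responsive) a
#' positive beats a negative when its score is lower.
#'
#' @param scores numeric vector of prediction scores.
#' @param labels logical (TRUE = positive, e.g. pCR) or a factor/character
#'   vector with levels `pCR`/`RD`.
#' @param positive_low if TRUE, low scores indicate the positive class.
#' @return The AU-ROC, a number in [0, 1].
#' @export
mann_whitney_auc <- function(scores, labels, positive_low = TRUE) {
  labels <- as_positive(labels)
  m <- sum(labels); n <- sum(!labels)
  if (m == 0L || n == 0L)
    stopf("both classes must be present (got %d positive, %d negative)", m, n)
  s <- if (positive_low) -scores else scores
  r <- rank(s)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- as.character(labels)
  if (!all(lab %in% c("pCR", "RD")))
    stopf("labels must be logical or pCR/RD")
  lab == "pCR"
}

#' ROC area with a DeLong confidence interval
#'
#' Computes the Mann-Whitney AU-ROC and its DeLong placement-value variance:
#' with placement values V10 (per positive, the fraction of negatives it
#' beats) and V01 (per negative), var(AUC) = var(V10)/m + var(V01)/n. A Wald
#' interval on the AUC scale is clipped to [0, 1]. When the placement
#' variance is zero (e.g. perfect separation) the interval collapses to the
#' point estimate and is flagged as degenerate.
#'
#' @inheritParams mann_whitney_auc
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @return An object of class `"roc_result"`: list with `auc`, `ci_low`,
#'   `ci_high`, `alpha`, `n_pos`, `n_neg`, `variance`, `degenerate`.
#' @export
delong_ci <- function(scores, labels, alpha = 0.05, positive_low = TRUE) {
  labels <- as_positive(labels)
  m <- sum(labels); n <- sum(!labels)
  if (m < 2L || n < 2L)
    stopf("DeLong CI needs >= 2 samples per class (got %d, %d)", m, n)
  s <- if (positive_low) -scores else scores
  pos <- s[labels]; neg <- s[!labels]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  variance <- stats::var(v10) / m + stats::var(v01) / n
  degenerate <- variance <= 0
  if (degenerate) {
    lo <- hi <- auc
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    half <- z * sqrt(variance)
    lo <- max(0, auc - half)
    hi <- min(1, auc + half)
  }
  structure(list(auc = auc, ci_low = lo, ci_high = hi, alpha = alpha,
                 n_pos = m, n_neg = n, variance = variance,
                 degenerate = degenerate),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AU-ROC %.2f (%d%% CI: %.2f-%.2f)%s  [n+ = %d, n- = %d]\n",
              x$auc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              if (x$degenerate) " [degenerate variance]" else "",
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param group_a,group_b numeric vectors (both nonempty).
#' @param exact override the automatic exact/asymptotic rule.
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact = NULL) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  if (is.null(exact))
    exact <- (length(group_a) + length(group_b) <= 12L) && !ties
  suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)$p.value)
}

#' Odds ratio of a 2x2 contingency table
#'
#' Closed-form odds ratio with a Wald confidence interval on the log scale,
#' for a binary exposure: `a` = positive & exposed, `b` = positive &
#' unexposed, `c` = negative & exposed, `d` = negative & unexposed. No
#' continuity correction is applied; any zero cell is an error.
#'
#' @param a,b,c,d nonnegative cell counts.
#' @param alpha two-sided error rate (default 0.05).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `p_value` (Wald),
#'   `n` (table total).
#' @examples
#' odds_ratio_2x2(8, 17, 20, 20)  # OR 0.47, CI 0.17-1.34
#' @export
odds_ratio_2x2 <- function(a, b, c, d, alpha = 0.05) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0))
    stopf("cell counts must be finite and >= 0")
  if (any(cells == 0))
    stopf("zero cell(s): %s (no continuity correction is applied)",
          paste(names(cells)[cells == 0], collapse = ", "))
  lor <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  list(odds_ratio = exp(lor),
       ci_low = exp(lor - z * se), ci_high = exp(lor + z * se),
       p_value = 2 * stats::pnorm(-abs(lor / se)),
       n = sum(cells))
}

# Numeric coding of clinical covariates:
# ER/PR/HER2 positive = 1; nodal N1-N3 = 1 vs N0 = 0; grade 3 = 1 vs 1&2 = 0;
# T ordinal 1-4; age and score continuous. "unknown" becomes NA.
code_covariates <- function(cohort) {
  bin <- function(v, one, zero) {
    out <- rep(NA_real_, length(v))
    out[v %in% one] <- 1
    out[v %in% zero] <- 0
    out
  }
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  if (!is.null(cohort$age)) out$age <- as.numeric(cohort$age)
  if (!is.null(cohort$er)) out$er <- bin(cohort$er, "positive", "negative")
  if (!is.null(cohort$pr)) out$pr <- bin(cohort$pr, "positive", "negative")
  if (!is.null(cohort$her2)) out$her2 <- bin(cohort$her2, "positive", "negative")
  if (!is.null(cohort$nodal))
    out$nodal <- bin(cohort$nodal, c("N1", "N2", "N3"), "N0")
  if (!is.null(cohort$t_stage)) {
    t <- match(as.character(cohort$t_stage), paste0("T", 1:4))
    out$t_stage <- as.numeric(t)
  }
  if (!is.null(cohort$grade)) out$grade <- bin(cohort$grade, "3", "1&2")
  if (!is.null(cohort$score)) out$score <- as.numeric(cohort$score)
  out
}

#' Logistic regression odds ratios for a clinical cohort
#'
#' Fits maximum-likelihood logistic regressions of the binary response on
#' clinical covariates and a prediction score, reporting Wald confidence
#' intervals and p-values on the odds-ratio scale. Covariate coding: ER, PR
#' and HER2 positive = 1; nodal N1-N3 = 1 vs N0 = 0; grade 3 = 1 vs 1&2 = 0;
#' tumor stage T as ordinal 1-4; age and score continuous. Rows with an
#' unknown value for any covariate in the model at hand are dropped
#' (complete-case, counted in the output); in univariate mode this happens
#' per covariate.
#'
#' @param outcome binary response: logical, 0/1, or pCR/RD.
#' @param covariates data.frame of clinical columns (any of `age`, `er`,
#'   `pr`, `her2`, `nodal`, `t_stage`, `grade`, `score`), raw coding as in
#'   the clinical CSV, or already-numeric columns.
#' @param mode `"univariate"` (one model per covariate) or `"multivariate"`
#'   (all covariates jointly).
#' @param alpha two-sided error rate for the Wald intervals.
#' @return data.frame with one row per covariate: `covariate`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `converged`, `n`.
#' @export
fit_logistic <- function(outcome, covariates,
                         mode = c("univariate", "multivariate"),
                         alpha = 0.05) {
  mode <- match.arg(mode)
  y <- if (is.logical(outcome)) as.integer(outcome)
       else if (is.numeric(outcome)) as.integer(outcome)
       else as.integer(as_positive(outcome))
  if (!all(y %in% 0:1)) stopf("outcome must be binary")
  x <- code_covariates(as.data.frame(covariates))
  if (ncol(x) == 0L) stopf("no recognized covariate columns")

  one_fit <- function(cols) {
    xx <- x[cols]
    cc <- stats::complete.cases(xx) & !is.na(y)
    n_used <- sum(cc)
    dropped <- length(y) - n_used
    if (dropped > 0)
      message(sprintf("fit_logistic: dropped %d row(s) with unknown %s",
                      dropped, paste(cols, collapse = "/")))
    dat <- cbind(.y = y[cc], xx[cc, , drop = FALSE])
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                 control = stats::glm.control(maxit = 50)))
    sm <- summary(fit)$coefficients
    z <- stats::qnorm(1 - alpha / 2)
    est <- sm[-1, 1]; se <- sm[-1, 2]; p <- sm[-1, 4]
    # complete or quasi-complete separation shows up as exploding |coef|/SE
    converged <- fit$converged && all(abs(est) < 15) && all(se < 100)
    data.frame(covariate = rownames(sm)[-1],
               odds_ratio = exp(est),
               ci_low = exp(est - z * se), ci_high = exp(est + z * se),
               p_value = p, converged = converged, n = n_used,
               row.names = NULL, stringsAsFactors = FALSE)
  }

  if (mode == "univariate") {
    out <- do.call(rbind, lapply(names(x), one_fit))
  } else {
    out <- one_fit(names(x))
  }
  out
}

#' Blinded-validation report for a scored patient cohort
#'
#' Given prediction scores and a clinical table, produces the full
#' validation battery: per treatment arm (and, within the first arm, per ER
#' status), the mean score by response with a two-sided Wilcoxon rank-sum
#' p-value and the AU-ROC with a DeLong confidence interval; plus
#' univariate and multivariate logistic odds-ratio tables per arm.
#' Subgroups with a single response class are skipped with a warning;
#' patients with unknown ER status are excluded from the ER subgroups.
#'
#' @param scores named numeric vector of prediction scores (names =
#'   sample ids).
#' @param cohort data.frame with columns `sample_id`, `response`
#'   (pCR/RD), `arm`, and the clinical covariates of [fit_logistic()].
#' @param alpha two-sided error rate.
#' @param positive_low TRUE if lower scores predict pCR.
#' @return An object of class `"mgp_validation"`: list with `subgroups`
#'   (each with `n`, `mean_pcr`, `mean_rd`, `wilcoxon_p`, `roc`) and
#'   `logistic` (per arm: `univariate`, `multivariate` tables).
#' @export
validate_cohort <- function(scores, cohort, alpha = 0.05,
                            positive_low = TRUE) {
  cohort <- as.data.frame(cohort)
  stopifnot(all(c("sample_id", "response", "arm") %in% names(cohort)))
  if (!all(cohort$sample_id %in% names(scores)))
    stopf("missing scores for sample(s): %s",
          paste(setdiff(cohort$sample_id, names(scores)), collapse = ", "))
  cohort$score <- unname(scores[cohort$sample_id])

  arms <- unique(cohort$arm)
  subsets <- list()
  for (a in arms) subsets[[a]] <- cohort[cohort$arm == a, ]
  # ER subgroups are analyzed within the main (largest) arm; patients with
  # unknown ER status fall outside both subgroups
  main_arm <- names(which.max(table(cohort$arm)))
  for (e in c("negative", "positive")) {
    nm <- sprintf("%s ER-%s", main_arm, e)
    subsets[[nm]] <- cohort[cohort$arm == main_arm & cohort$er == e, ]
  }

  subgroups <- list()
  for (nm in names(subsets)) {
    d <- subsets[[nm]]
    pos <- d$response == "pCR"
    if (nrow(d) == 0L || length(unique(d$response)) < 2L) {
      warnf("subgroup '%s' skipped: fewer than two response classes", nm)
      next
    }
    subgroups[[nm]] <- list(
      n = nrow(d), n_pcr = sum(pos),
      mean_pcr = mean(d$score[pos]), mean_rd = mean(d$score[!pos]),
      wilcoxon_p = wilcoxon_rank_sum(d$score[pos], d$score[!pos]),
      roc = delong_ci(d$score, pos, alpha = alpha,
                      positive_low = positive_low))
  }

  covnames <- intersect(c("age", "er", "pr", "nodal", "t_stage", "grade",
                          "score"), names(cohort))
  logistic <- list()
  for (a in arms) {
    d <- subsets[[a]]
    if (length(unique(d$response)) < 2L) next
    logistic[[a]] <- list(
      univariate = fit_logistic(d$response, d[covnames], "univariate",
                                alpha = alpha),
      multivariate = fit_logistic(d$response, d[covnames], "multivariate",
                                  alpha = alpha))
  }
  structure(list(subgroups = subgroups, logistic = logistic, alpha = alpha),
            class = "mgp_validation")
}

#' @export
print.mgp_validation <- function(x, ...) {
  cat("Blinded validation report\n")
  for (nm in names(x$subgroups)) {
    s <- x$subgroups[[nm]]
    cat(sprintf("  %s (n=%d, pCR=%d): mean score pCR %.3f vs RD %.3f, Wilcoxon p=%.3g\n",
                nm, s$n, s$n_pcr, s$mean_pcr, s$mean_rd, s$wilcoxon_p))
    cat(sprintf("    AU-ROC %.2f (%.0f%% CI %.2f-%.2f)\n", s$roc$auc,
                100 * (1 - s$roc$alpha), s$roc$ci_low, s$roc$ci_high))
  }
  for (a in names(x$logistic)) {
    cat(sprintf("  logistic regression, %s arm (univariate):\n", a))
    u <- x$logistic[[a]]$univariate
    for (i in seq_len(nrow(u)))
      cat(sprintf("    %-8s OR %.2f (%.2f, %.2f) p=%.2g%s\n", u$covariate[i],
                  u$odds_ratio[i], u$ci_low[i], u$ci_high[i], u$p_value[i],
                  if (!u$converged[i]) " [not converged]" else ""))
  }
  invisible(x)
}
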