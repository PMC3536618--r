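#' Fit a multi-gene predictor of chemosensitivity
#'
#' `mgp_fit()` is the front door of the package: given a log2 expression
#' matrix for a cell-line panel and the panel's dose-response AUC scores, it
#' runs the full supervised principal-components regression recipe:
#'
#' 1. non-specific probe filtering on the unstandardized log2 values
#'    ([filter_probes()]),
#' 2. per-sample standardization to mean 0, sd 1 ([standardize_samples()]),
#' 3. univariate feature screening against the AUC scores
#'    ([screen_features()]),
#' 4. selection of probes whose absolute feature score reaches a threshold,
#'    chosen by k-fold cross-validation when not supplied
#'    ([cv_select_threshold()]),
#' 5. first principal component of the selected probe submatrix, and an
#'    ordinary least-squares regression of AUC on that component
#'    ([fit_supervised_pc()]).
#'
#' The loadings' sign is fixed so the regression slope is nonnegative: a
#' lower prediction score always means greater predicted sensitivity (and,
#' for patients, a higher predicted likelihood of pathologic complete
#' response).
#'
#' @param x probes x samples log2 expression matrix (unfiltered,
#'   unstandardized unless the corresponding steps are disabled).
#' @param y named numeric vector of AUC sensitivity scores, one per sample.
#' @param threshold fixed feature-score threshold; `NULL` (default) selects
#'   one by cross-validation.
#' @param candidate_thresholds grid for the cross-validated search; `NULL`
#'   uses 40 evenly spaced values between the 50th and 99th percentile of
#'   the absolute feature scores.
#' @param k number of cross-validation folds (default 10).
#' @param rule threshold-selection rule for the cross-validated search,
#'   `"1se"` (default) or `"max"`; see [cv_select_threshold()].
#' @param seed integer seed for the fold partition.
#' @param filter apply non-specific filtering (default TRUE).
#' @param iqr_min,median_min filtering thresholds, see [filter_probes()].
#' @param standardize apply per-sample standardization (default TRUE).
#' @return An object of class `"mgp"`; see Details. Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`.
#' @details The returned object carries `selected_probe_ids`, unit-norm
#'   `loadings`, training `probe_means`, `intercept` and `slope` of the
#'   scoring regression, the screening table (`screen`), the
#'   cross-validation curve (`cv`, when run), and preprocessing provenance
#'   used by `predict` to process new cohorts identically.
#' @examples
#' sim <- generate_cell_line_panel(panel_config(seed = 1))
#' fit <- mgp_fit(sim$expression, sim$auc, threshold = 4)
#' fit
#' head(predict(fit, sim$expression))
#' @export
mgp_fit <- function(x, y, threshold = NULL, candidate_thresholds = NULL,
                    k = 10, rule = c("1se", "max"), seed = 1, filter = TRUE,
                    iqr_min = 0.5, median_min = log2(100),
                    standardize = TRUE) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(x))
  if (is.null(names(y)) || !setequal(colnames(x), names(y)))
    stopf("sample ids of x and names of y must coincide")
  y <- y[colnames(x)]
  cl <- match.call()

  report <- NULL
  if (filter) {
    f <- filter_probes(x, iqr_min = iqr_min, median_min = median_min)
    x <- f$matrix
    report <- f$report
    if (nrow(x) == 0L) stopf("no probes survive filtering")
  }
  if (standardize) x <- standardize_samples(x)

  cv <- NULL
  if (is.null(threshold)) {
    cv <- cv_select_threshold(x, y, candidate_thresholds = candidate_thresholds,
                              k = k, seed = seed, rule = rule)
    threshold <- cv$threshold
  }
  model <- fit_supervised_pc(x, y, threshold)
  model$cv <- cv
  model$preprocessing <- list(
    filtered = filter, iqr_min = if (filter) iqr_min else NA_real_,
    median_min = if (filter) median_min else NA_real_,
    kept_probes = rownames(x), standardized = standardize,
    filter_report = report)
  model$seed <- seed
  model$call <- cl
  model
}

#' Supervised first-principal-component regression on preselected data
#'
#' The core estimator behind [mgp_fit()], for callers who have already
#' filtered and standardized their matrix. Probes with absolute feature
#' score at or above `threshold` are selected; the first right-singular
#' direction of the probe-centered selected submatrix (samples as
#' observations) provides unit-norm loadings; AUC is regressed on the
#' resulting component scores by ordinary least squares. Loadings are
#' negated if needed so the slope is nonnegative.
#'
#' @param x probes x samples matrix, preprocessed.
#' @param y named numeric AUC vector aligned to the samples of `x`.
#' @param threshold feature-score threshold (absolute value).
#' @param screen optional precomputed [screen_features()] table for `x`, `y`.
#' @return An object of class `"mgp"` (without preprocessing provenance,
#'   which [mgp_fit()] attaches).
#' @export
fit_supervised_pc <- function(x, y, threshold, screen = NULL) {
  stopifnot(is.matrix(x))
  y <- y[colnames(x)]
  if (is.null(screen)) screen <- screen_features(x, y)
  sel <- screen$probe_id[abs(screen$score) >= threshold]
  if (length(sel) == 0L)
    stopf("no probe reaches |score| >= %g (max observed %g)",
          threshold, max(abs(screen$score)))
  xs <- x[sel, , drop = FALSE]
  mu <- rowMeans(xs)
  a <- t(xs - mu)                      # samples x selected probes
  sv <- svd(a, nu = 1L, nv = 1L)
  loadings <- drop(sv$v)
  pc <- drop(a %*% loadings)
  ols <- stats::lm.fit(cbind(1, pc), y)
  intercept <- unname(ols$coefficients[1])
  slope <- unname(ols$coefficients[2])
  if (is.na(slope)) slope <- 0         # degenerate: constant component
  if (slope < 0) {
    loadings <- -loadings
    pc <- -pc
    slope <- -slope
  }
  names(loadings) <- sel
  fitted <- intercept + slope * pc
  names(fitted) <- colnames(x)
  structure(
    list(selected_probe_ids = sel, loadings = loadings, probe_means = mu,
         intercept = intercept, slope = slope, threshold = threshold,
         screen = screen, cv = NULL,
         preprocessing = list(filtered = FALSE, iqr_min = NA_real_,
                              median_min = NA_real_, kept_probes = rownames(x),
                              standardized = FALSE, filter_report = NULL),
         fitted = fitted, y = y, n = ncol(x), call = sys.call()),
    class = "mgp")
}

#' Choose the feature-score threshold by cross-validation
#'
#' Samples are split into `k` seeded folds of sizes differing by at most one.
#' For each fold and candidate threshold, screening and the first-component
#' fit are redone on the training split alone; held-out samples are projected
#' onto the training loadings and the squared Pearson correlation between
#' their component scores and their AUC values is recorded. With
#' `rule = "1se"` (default) the winner is the largest candidate whose
#' fold-mean statistic lies within one standard error of the maximum — the
#' usual one-standard-error parsimony rule, robust to the long flat plateau
#' these curves typically show. `rule = "max"` takes the plain argmax (ties
#' to the smallest candidate). A candidate selecting zero probes in some
#' training split contributes 0 for that fold.
#'
#' @param x probes x samples matrix, preprocessed.
#' @param y named numeric AUC vector.
#' @param candidate_thresholds numeric grid; `NULL` for the default grid
#'   (40 values between the 50th and 99th percentile of absolute scores).
#' @param k number of folds.
#' @param seed seed for the fold partition.
#' @param rule `"1se"` (default) or `"max"`, see Details.
#' @return List with `threshold`, `curve` (data.frame of `threshold`,
#'   `mean_stat`, `se_stat`), `k`, `seed` and `rule`.
#' @export
cv_select_threshold <- function(x, y, candidate_thresholds = NULL, k = 10,
                                seed = 1, rule = c("1se", "max")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(x))
  y <- y[colnames(x)]
  n <- ncol(x)
  if (n < k) stopf("need at least k = %d samples, got %d", k, n)
  if (is.null(candidate_thresholds)) {
    sc <- abs(screen_features(x, y)$score)
    qs <- stats::quantile(sc, c(0.50, 0.99), type = 7, names = FALSE)
    candidate_thresholds <- seq(qs[1], qs[2], length.out = 40)
  }
  if (length(candidate_thresholds) < 1L) stopf("empty candidate grid")

  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  stat <- matrix(0, nrow = k, ncol = length(candidate_thresholds))
  for (f in seq_len(k)) {
    tr <- folds != f
    scr <- screen_features(x[, tr, drop = FALSE], y[tr])
    for (ci in seq_along(candidate_thresholds)) {
      sel <- scr$probe_id[abs(scr$score) >= candidate_thresholds[ci]]
      if (length(sel) == 0L) next     # contributes 0 for this fold
      xs <- x[sel, tr, drop = FALSE]
      mu <- rowMeans(xs)
      sv <- svd(t(xs - mu), nu = 0L, nv = 1L)
      v <- drop(sv$v)
      pc_ho <- drop(crossprod(x[sel, !tr, drop = FALSE] - mu, v))
      y_ho <- y[!tr]
      if (length(pc_ho) >= 2L && stats::sd(pc_ho) > 0 && stats::sd(y_ho) > 0)
        stat[f, ci] <- stats::cor(pc_ho, y_ho)^2
    }
  }
  mean_stat <- colMeans(stat)
  se_stat <- apply(stat, 2L, stats::sd) / sqrt(k)
  if (all(mean_stat == 0))
    stopf("cross-validation statistic is zero everywhere; try a lower threshold grid")
  best <- which.max(mean_stat)        # ties: first = smallest candidate
  pick <- if (rule == "1se")
    max(which(mean_stat >= mean_stat[best] - se_stat[best])) else best
  list(threshold = candidate_thresholds[pick],
       curve = data.frame(threshold = candidate_thresholds,
                          mean_stat = mean_stat, se_stat = se_stat),
       k = k, seed = seed, rule = rule)
}

#' Score new samples with a fitted predictor
#'
#' New arrays are preprocessed according to the model's provenance: the
#' matrix is restricted to the training probe universe (or, with
#' `universe = "model"`, to the model probes only), each array is
#' standardized over that universe, and samples are projected onto the
#' model loadings. The score is `intercept + slope * projection`; lower
#' scores mean greater predicted sensitivity.
#'
#' Model probes absent from `newdata` are tolerated up to 50%: the loadings
#' are restricted to the available probes and renormalized to unit norm,
#' with a warning. Above 50% missing, scoring errors out.
#'
#' @param object an `"mgp"` fit.
#' @param newdata probes x samples log2 matrix; `NULL` returns the in-sample
#'   fitted values.
#' @param universe `"training"` (default) standardizes each array over the
#'   training filter universe present on the new platform; `"model"` uses
#'   the model probes only.
#' @param ... ignored.
#' @return Named numeric vector of prediction scores.
#' @export
predict.mgp <- function(object, newdata = NULL,
                        universe = c("training", "model"), ...) {
  if (is.null(newdata)) return(object$fitted)
  universe <- match.arg(universe)
  stopifnot(is.matrix(newdata))
  uni <- if (universe == "training") object$preprocessing$kept_probes
         else object$selected_probe_ids
  ip <- intersect_probes(newdata, uni)
  if (nrow(ip$matrix) == 0L) stopf("no model universe probes found in newdata")
  xs <- if (isTRUE(object$preprocessing$standardized))
    standardize_samples(ip$matrix) else ip$matrix

  probes <- object$selected_probe_ids
  missing <- setdiff(probes, rownames(xs))
  loadings <- object$loadings
  mu <- object$probe_means
  if (length(missing) > 0L) {
    frac <- length(missing) / length(probes)
    if (frac > 0.5)
      stopf("%d of %d model probes (%.0f%%) missing from newdata",
            length(missing), length(probes), 100 * frac)
    warnf("%d of %d model probes missing from newdata; loadings restricted and renormalized",
          length(missing), length(probes))
    keepp <- setdiff(probes, missing)
    loadings <- loadings[keepp]
    loadings <- loadings / sqrt(sum(loadings^2))
    mu <- mu[keepp]
    probes <- keepp
  }
  proj <- drop(crossprod(xs[probes, , drop = FALSE] - mu, loadings))
  scores <- object$intercept + object$slope * proj
  names(scores) <- colnames(newdata)
  scores
}

#' @export
print.mgp <- function(x, ...) {
  cat("Multi-gene predictor (supervised principal components)\n")
  cat(sprintf("  %d probes selected at |score| >= %.4g%s\n",
              length(x$selected_probe_ids), x$threshold,
              if (!is.null(x$cv)) sprintf(" (chosen by %d-fold CV)", x$cv$k)
              else ""))
  cat(sprintf("  score = %.4g + %.4g * PC1   (lower score = more sensitive)\n",
              x$intercept, x$slope))
  cat(sprintf("  trained on %d samples\n", x$n))
  invisible(x)
}

#' @export
summary.mgp <- function(object, q_cut = 0.01, ...) {
  scr <- object$screen
  r2 <- if (stats::sd(object$y) > 0)
    stats::cor(object$fitted, object$y)^2 else NA_real_
  structure(
    list(n = object$n, n_screened = nrow(scr),
         n_significant = sum(scr$q_value < q_cut), q_cut = q_cut,
         n_selected = length(object$selected_probe_ids),
         threshold = object$threshold, cv = !is.null(object$cv),
         intercept = object$intercept, slope = object$slope,
         r_squared = r2),
    class = "summary.mgp")
}

#' @export
print.summary.mgp <- function(x, ...) {
  cat("Multi-gene predictor summary\n")
  cat(sprintf("  samples: %d   probes screened: %d\n", x$n, x$n_screened))
  cat(sprintf("  probes with q < %g: %d\n", x$q_cut, x$n_significant))
  cat(sprintf("  probes in model: %d (|score| >= %.4g%s)\n", x$n_selected,
              x$threshold, if (x$cv) ", cross-validated" else ", fixed"))
  cat(sprintf("  scoring: %.4g + %.4g * PC1;  in-sample R^2 = %.3f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
coef.mgp <- function(object, what = c("regression", "loadings"), ...) {
  what <- match.arg(what)
  if (what == "regression")
    c("(Intercept)" = object$intercept, PC1 = object$slope)
  else object$loadings
}

#' @export
fitted.mgp <- function(object, ...) object$fitted

#' @export
residuals.mgp <- function(object, ...) object$y - object$fitted

#' @export
plot.mgp <- function(x, ...) {
  has_cv <- !is.null(x$cv)
  if (has_cv) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    plot(x$cv$curve$threshold, x$cv$curve$mean_stat, type = "b",
         xlab = "feature-score threshold",
         ylab = "mean held-out squared correlation",
         main = sprintf("%d-fold CV", x$cv$k), ...)
    graphics::abline(v = x$threshold, lty = 2)
  }
  plot(x$fitted, x$y, xlab = "prediction score", ylab = "observed AUC",
       main = "training fit", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Serialize / restore a fitted predictor as JSON
#'
#' Writes the selected probes, loadings, training probe means, scoring
#' coefficients, threshold and preprocessing provenance with full double
#' precision, so a restored model scores identically.
#'
#' @param model an `"mgp"` fit.
#' @param path JSON file path.
#' @param extra optional named list of additional metadata fields (e.g. a
#'   workflow config hash) stored alongside the model.
#' @export
write_mgp <- function(model, path, extra = NULL) {
  stopifnot(inherits(model, "mgp"))
  pp <- model$preprocessing
  obj <- list(
    format = "chemoMGP/mgp-model",
    selected_probe_ids = model$selected_probe_ids,
    loadings = unname(model$loadings),
    probe_means = unname(model$probe_means),
    intercept = model$intercept, slope = model$slope,
    threshold = model$threshold,
    preprocessing = list(filtered = pp$filtered, iqr_min = pp$iqr_min,
                         median_min = pp$median_min,
                         kept_probes = pp$kept_probes,
                         standardized = pp$standardized),
    seed = model$seed, n_train = model$n)
  if (!is.null(extra)) obj <- c(obj, extra)
  # digits = I(17): decimal digits sufficient for exact double round-trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_mgp
#' @param path JSON file path.
#' @export
read_mgp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "chemoMGP/mgp-model"))
    stopf("%s is not a serialized mgp model", path)
  pp <- obj$preprocessing
  structure(
    list(selected_probe_ids = obj$selected_probe_ids,
         loadings = stats::setNames(obj$loadings, obj$selected_probe_ids),
         probe_means = stats::setNames(obj$probe_means, obj$selected_probe_ids),
         intercept = obj$intercept, slope = obj$slope,
         threshold = obj$threshold,
         screen = NULL, cv = NULL,
         preprocessing = list(filtered = pp$filtered,
                              iqr_min = if (is.null(pp$iqr_min)) NA_real_ else pp$iqr_min,
                              median_min = if (is.null(pp$median_min)) NA_real_ else pp$median_min,
                              kept_probes = pp$kept_probes,
                              standardized = pp$standardized,
                              filter_report = NULL),
         fitted = NULL, y = NULL, n = obj$n_train,
         seed = obj$seed, call = NULL),
    class = "mgp")
}
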