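#' Univariate feature screening against a sensitivity profile
#'
#' For each probe j the feature score is the standardized univariate
#' regression coefficient
#' \deqn{s_j = (x_j - \bar x_j) \cdot (y - \bar y) / \lVert x_j - \bar x_j \rVert,}
#' the scale used by supervised principal-components methodology. Two-sided
#' p-values come from the univariate regression t-test on n - 2 degrees of
#' freedom and q-values from Benjamini-Hochberg.
#'
#' @param x probes x samples expression matrix (filtered and standardized).
#' @param y named numeric vector of sensitivity scores (AUC); names must match
#'   the sample ids of `x` as a set.
#' @return data.frame with columns `probe_id`, `score`, `p_value`, `q_value`,
#'   in the probe order of `x`.
#' @export
screen_features <- function(x, y) {
  stopifnot(is.matrix(x))
  if (is.null(names(y)) || !setequal(colnames(x), names(y)))
    stopf("sample ids of x and names of y must coincide")
  y <- y[colnames(x)]
  n <- ncol(x)
  if (n < 3L) stopf("screening needs at least 3 samples, got %d", n)
  xc <- x - rowMeans(x)
  yc <- y - mean(y)
  xnorm <- sqrt(rowSums(xc^2))
  if (any(xnorm == 0))
    stopf("zero-variance probe(s) (filter first): %s",
          paste(rownames(x)[xnorm == 0], collapse = ", "))
  score <- drop(xc %*% yc) / xnorm
  ynorm <- sqrt(sum(yc^2))
  if (ynorm == 0) stopf("sensitivity scores are constant")
  r <- pmin(1, pmax(-1, score / ynorm))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(0, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[r^2 >= 1] <- 0
  data.frame(probe_id = rownames(x), score = score, p_value = p,
             q_value = benjamini_hochberg(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; results are in [0, 1] and
#' monotone in p-value rank.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
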