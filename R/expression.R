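#' Read a log2 expression matrix
#'
#' Tab-delimited text: first column holds probe ids, the header row holds
#' sample ids (a GCT-like layout without the version banner). Values are
#' assumed to be post-summarization log2 intensities; set `log2_transform`
#' for matrices on the linear scale.
#'
#' @param path path to the tab-delimited file.
#' @param log2_transform if TRUE, apply log2 after checking all values are
#'   strictly positive.
#' @return Numeric matrix, probes in rows, samples in columns, with dimnames.
#' @export
load_expression_matrix <- function(path, log2_transform = FALSE) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes))
    stopf("%s: duplicate probe id(s): %s", path,
          paste(unique(probes[duplicated(probes)]), collapse = ", "))
  vals <- df[-1]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stopf("%s: non-numeric value at probe '%s', sample '%s'",
            path, probes[i], names(vals)[j])
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- probes
  if (anyDuplicated(colnames(m)))
    stopf("%s: duplicate sample id(s)", path)
  if (log2_transform) {
    if (any(m <= 0))
      stopf("%s: log2_transform requires strictly positive values", path)
    m <- log2(m)
  }
  m
}

#' Write an expression matrix
#'
#' Writes the tab-delimited layout read by [load_expression_matrix()], with
#' full double precision so the round trip is exact.
#'
#' @param m numeric matrix with probe row names and sample column names.
#' @param path output file path.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c("probe_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format_full(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Non-specific probe filtering
#'
#' Removes probes with small variation (interquartile range below `iqr_min`)
#' or low expression (median below `median_min`) across samples, computed on
#' the unstandardized log2 values. A probe is kept iff IQR >= `iqr_min` AND
#' median >= `median_min`; ties at either threshold are kept. A probe failing
#' both rules is reported under low variation only (first rule wins).
#' Quantiles use the linear-interpolation (type 7) convention.
#'
#' @param m probes x samples log2 matrix (>= 2 samples).
#' @param iqr_min minimum interquartile range (default 0.5).
#' @param median_min minimum median log2 expression (default log2(100)).
#' @return A list with `matrix` (the kept rows) and `report`, a
#'   `"filter_report"` carrying the kept and dropped probe ids and thresholds.
#' @export
filter_probes <- function(m, iqr_min = 0.5, median_min = log2(100)) {
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  iqr <- apply(m, 1L, stats::IQR, type = 7)
  med <- apply(m, 1L, stats::median)
  low_var <- iqr < iqr_min
  low_expr <- !low_var & med < median_min
  keep <- !low_var & !low_expr
  report <- structure(
    list(kept_probes = rownames(m)[keep],
         dropped_low_variation = rownames(m)[low_var],
         dropped_low_expression = rownames(m)[low_expr],
         iqr_min = iqr_min, median_min = median_min),
    class = "filter_report")
  list(matrix = m[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> kept %d probes; dropped %d ",
                     "(IQR < %.3g) + %d (median < %.4g)\n"),
              length(x$kept_probes), length(x$dropped_low_variation),
              x$iqr_min, length(x$dropped_low_expression), x$median_min))
  invisible(x)
}

#' Per-sample standardization
#'
#' Centers and scales each sample (column) to mean zero and standard
#' deviation one across the current probe universe, using the n-1 denominator.
#'
#' @param m probes x samples matrix.
#' @return Matrix of the same shape; probe order preserved.
#' @export
standardize_samples <- function(m) {
  stopifnot(is.matrix(m))
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    stopf("cannot standardize constant sample column(s): %s",
          paste(colnames(m)[sds == 0 | !is.finite(sds)], collapse = ", "))
  out <- scale(m, center = TRUE, scale = TRUE)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Restrict a matrix to a probe list
#'
#' Returns the rows of `m` present in `probe_ids`, in the order of
#' `probe_ids`, together with the requested probes that are absent —
#' the reconciliation step when training and scoring platforms differ.
#'
#' @param m probes x samples matrix.
#' @param probe_ids character vector of requested probes.
#' @return List with `matrix` (possibly zero rows) and `missing`.
#' @export
intersect_probes <- function(m, probe_ids) {
  present <- probe_ids[probe_ids %in% rownames(m)]
  list(matrix = m[present, , drop = FALSE],
       missing = setdiff(probe_ids, present))
}
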