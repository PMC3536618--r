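#' Construct a dose-response plate
#'
#' A plate holds the raw surviving-cell counts for one cell line treated with
#' a ten-step serial dilution of a drug combination, in replicate wells, plus
#' untreated control wells. Doses are ordinal indices 1..10; absolute
#' concentrations, if known, can be attached as metadata but play no role in
#' scoring.
#'
#' @param cell_line_id character scalar identifying the cell line.
#' @param treated data.frame with columns `dose_index` (integers 1..10),
#'   `count` (nonnegative surviving-cell counts) and optionally `well_id`.
#' @param control numeric vector of nonnegative control-well counts (>= 1 well).
#' @param dose_metadata optional vector of length 10 describing the
#'   concentrations behind each dose index (stored, never used).
#' @return An object of class `"dr_plate"`.
#' @seealso [compute_survival_fractions()], [compute_auc()], [load_plates()]
#' @export
dr_plate <- function(cell_line_id, treated, control, dose_metadata = NULL) {
  stopifnot(is.character(cell_line_id), length(cell_line_id) == 1L)
  treated <- as.data.frame(treated)
  if (!all(c("dose_index", "count") %in% names(treated)))
    stopf("plate '%s': treated wells need columns dose_index and count",
          cell_line_id)
  if (is.null(treated$well_id))
    treated$well_id <- paste0("w", seq_len(nrow(treated)))
  di <- treated$dose_index
  if (!all(di == as.integer(di)) || any(di < 1L) || any(di > 10L))
    stopf("plate '%s': dose_index must be integers in 1..10", cell_line_id)
  missing_doses <- setdiff(1:10, unique(di))
  if (length(missing_doses))
    stopf("plate '%s': missing dose indices %s", cell_line_id,
          paste(missing_doses, collapse = ", "))
  if (length(control) < 1L)
    stopf("plate '%s': at least one control well is required", cell_line_id)
  counts <- c(treated$count, control)
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("plate '%s': all well counts must be finite and >= 0", cell_line_id)
  structure(
    list(cell_line_id = cell_line_id,
         treated = treated[c("dose_index", "well_id", "count")],
         control = as.numeric(control),
         dose_metadata = dose_metadata),
    class = "dr_plate")
}

#' @export
print.dr_plate <- function(x, ...) {
  cat(sprintf("<dr_plate> %s: %d treated wells over 10 doses, %d controls\n",
              x$cell_line_id, nrow(x$treated), length(x$control)))
  invisible(x)
}

#' Survival fractions from a plate
#'
#' The survival fraction at dose i is the mean surviving-cell count across the
#' treated wells at that dose divided by the mean count across the control
#' wells. Values above 1 (treated wells outgrowing controls) are retained.
#'
#' @param plate a [dr_plate()].
#' @return An object of class `"survival_curve"`: a list with `cell_line_id`
#'   and `sf`, a numeric vector of length 10.
#' @export
compute_survival_fractions <- function(plate) {
  stopifnot(inherits(plate, "dr_plate"))
  mc <- mean(plate$control)
  if (!is.finite(mc) || mc <= 0)
    stopf("plate '%s': mean control count must be > 0 (got %s)",
          plate$cell_line_id, format(mc))
  sf <- vapply(1:10, function(i) {
    mean(plate$treated$count[plate$treated$dose_index == i]) / mc
  }, numeric(1))
  structure(list(cell_line_id = plate$cell_line_id, sf = sf),
            class = "survival_curve")
}

#' Dose-response AUC sensitivity score
#'
#' The sensitivity score is the plain sum of the ten survival fractions
#' (no trapezoid rule, no dose weighting). A lower score means greater
#' sensitivity to the treatment.
#'
#' @param curve a `"survival_curve"` or a numeric vector of length 10.
#' @return The AUC score, a single nonnegative number.
#' @export
compute_auc <- function(curve) {
  sf <- if (inherits(curve, "survival_curve")) curve$sf else as.numeric(curve)
  if (length(sf) != 10L) stopf("a survival curve has exactly 10 doses, got %d",
                               length(sf))
  if (any(!is.finite(sf))) stopf("non-finite survival fraction at dose %s",
                                 paste(which(!is.finite(sf)), collapse = ", "))
  sum(sf)
}

#' Read dose-response plates from CSV
#'
#' Expects columns `cell_line_id`, `dose_index` (0 = control well, 1..10 =
#' treated), `well_id`, `count`, one row per well. Lines starting with `#`
#' are ignored.
#'
#' @param path path to the plate CSV file.
#' @return A named list of [dr_plate()] objects, one per cell line.
#' @export
load_plates <- function(path) {
  if (!file.exists(path)) stopf("plate file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("cell_line_id", "dose_index", "well_id", "count")
  if (!all(required %in% names(df)))
    stopf("plate file %s: missing columns %s", path,
          paste(setdiff(required, names(df)), collapse = ", "))
  if (nrow(df) == 0L) {
    warnf("plate file %s contains no wells", path)
    return(list())
  }
  bad <- which(!is.finite(df$count) | !is.finite(df$dose_index) |
                 df$dose_index < 0 | df$dose_index > 10 |
                 df$dose_index != as.integer(df$dose_index))
  if (length(bad))
    stopf("plate file %s: malformed row(s) at data line %s", path,
          paste(bad, collapse = ", "))
  key <- paste(df$cell_line_id, df$dose_index, df$well_id)
  if (anyDuplicated(key))
    stopf("plate file %s: duplicate (cell_line, dose, well): %s", path,
          paste(unique(key[duplicated(key)]), collapse = "; "))
  plates <- lapply(split(df, df$cell_line_id), function(d) {
    dr_plate(d$cell_line_id[1],
             treated = d[d$dose_index > 0, c("dose_index", "well_id", "count")],
             control = d$count[d$dose_index == 0])
  })
  plates[unique(df$cell_line_id)]
}

#' Write dose-response plates to CSV
#'
#' Inverse of [load_plates()]; control wells are written with `dose_index` 0.
#'
#' @param plates list of [dr_plate()] objects.
#' @param path output file path.
#' @export
write_plates <- function(plates, path) {
  rows <- lapply(plates, function(p) {
    rbind(
      data.frame(cell_line_id = p$cell_line_id, dose_index = 0L,
                 well_id = paste0("c", seq_along(p$control)),
                 count = p$control),
      data.frame(cell_line_id = p$cell_line_id,
                 dose_index = p$treated$dose_index,
                 well_id = p$treated$well_id, count = p$treated$count))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sensitivity profiles: AUC score per cell line
#'
#' A sensitivity profile is a named numeric vector mapping cell-line ids to
#' dose-response AUC scores. `sensitivity_profile()` computes one from plates;
#' the read/write pair uses a two-column CSV (`cell_line_id`, `auc`).
#'
#' @param plates list of [dr_plate()] objects.
#' @return Named numeric vector of AUC scores.
#' @export
sensitivity_profile <- function(plates) {
  vapply(plates, function(p) compute_auc(compute_survival_fractions(p)),
         numeric(1), USE.NAMES = TRUE)
}

#' @rdname sensitivity_profile
#' @param profile named numeric vector of AUC scores.
#' @param path file path.
#' @export
write_sensitivity_profile <- function(profile, path) {
  df <- data.frame(cell_line_id = names(profile),
                   auc = format_full(unname(profile)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sensitivity_profile
#' @export
read_sensitivity_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("cell_line_id", "auc") %in% names(df)))
    stopf("sensitivity profile %s: need columns cell_line_id, auc", path)
  stats::setNames(as.numeric(df$auc), df$cell_line_id)
}
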