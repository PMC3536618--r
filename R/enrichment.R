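#' Read a gene-set collection from a GMT file
#'
#' Broad GMT dialect: one set per tab-delimited line — name, description,
#' then member gene symbols. Members are uppercased and de-duplicated
#' within each set.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors (class `"gene_set_collection"`),
#'   with the path kept as a `provenance` attribute.
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stopf("%s: line %s has fewer than 3 fields", path,
          paste(short, collapse = ", "))
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stopf("%s: duplicate set name(s): %s", path,
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  structure(sets, provenance = path, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Permutation-based over-representation of a gene list
#'
#' For each gene set, the observed statistic is the overlap between the
#' selected genes and the set (both restricted to the universe). The null
#' draws `|selected|` genes uniformly without replacement from the universe
#' `n_perm` times; the p-value is `(1 + #{overlap >= observed}) / (1 +
#' n_perm)` (never exactly zero). Benjamini-Hochberg q-values are computed
#' across sets and a set is flagged enriched at q < 0.1.
#'
#' @param selected character vector of selected gene symbols (subset of
#'   `universe`).
#' @param universe character vector: all genes eligible for selection.
#' @param sets a [load_gmt()] collection or named list of symbol vectors.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param q_cut enrichment call threshold on the q-value (default 0.1).
#' @return data.frame with columns `set`, `size`, `overlap`, `p_value`,
#'   `q_value`, `enriched`.
#' @export
enrichment_qvalues <- function(selected, universe, sets, n_perm = 1000,
                               seed = 1, q_cut = 0.1) {
  selected <- unique(toupper(selected))
  universe <- unique(toupper(universe))
  if (n_perm < 100) stopf("n_perm must be >= 100")
  offenders <- setdiff(selected, universe)
  if (length(offenders))
    stopf("selected genes not in universe: %s",
          paste(offenders, collapse = ", "))
  if (length(sets) == 0L) stopf("empty gene-set collection")
  sets_u <- lapply(sets, function(s) intersect(toupper(s), universe))
  observed <- vapply(sets_u, function(s) length(intersect(s, selected)),
                     integer(1))
  k <- length(selected)
  member <- lapply(sets_u, function(s) universe %in% s)
  exceed <- integer(length(sets_u))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(universe), k)
      for (j in seq_along(sets_u))
        if (sum(member[[j]][idx]) >= observed[j]) exceed[j] <- exceed[j] + 1L
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  q <- benjamini_hochberg(p)
  data.frame(set = names(sets_u), size = lengths(sets_u),
             overlap = observed, p_value = p, q_value = q,
             enriched = q < q_cut, row.names = NULL,
             stringsAsFactors = FALSE)
}
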