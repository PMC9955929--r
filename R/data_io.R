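# CSV/TSV matrix I/O and JSON selection reports. Matrices are stored samples
# in rows, features in columns, RFC-4180 CSV with a header row, "." decimal,
# UTF-8. Loading is strict: missing or non-numeric feature cells abort (this
# method has no missing-data model; silent imputation would change results
# invisibly), rows are never dropped and column order is preserved.

#' Read a samples-by-features matrix with class labels
#'
#' @param path Path to a delimited text file with a header row.
#' @param label_col Name of the label column (default `"class"`).
#' @param delim Field delimiter; `NULL` (default) picks `"\t"` for `.tsv`
#'   files and `","` otherwise.
#' @param id_col Optional sample-identifier column, kept as character.
#' @return A tibble with the label column as a factor, the optional id column
#'   as character, and all remaining columns numeric (validated).
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_feature_matrix(synth_benchmark(n_per_class = 4, n_noise = 2, seed = 1), p)
#' d <- read_feature_matrix(p)
#' @export
read_feature_matrix <- function(path, label_col = "class", delim = NULL,
                                id_col = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, name_repair = "minimal")
  nm <- names(raw)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate feature names in header: %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (!label_col %in% nm) {
    abort(sprintf("label column '%s' not present in %s.", label_col, path))
  }
  feats <- setdiff(nm, c(label_col, id_col))
  out <- raw
  for (f in feats) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    bad <- which(is.na(v) & !is.na(out[[f]]))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric value '%s' at row %d of column '%s'.",
                    out[[f]][bad[1]], bad[1], f))
    }
    if (anyNA(v)) {
      abort(sprintf("missing value at row %d of column '%s'; refusing to load.",
                    which(is.na(v))[1], f))
    }
    out[[f]] <- v
  }
  out[[label_col]] <- factor(out[[label_col]])
  # validate invariants (n >= 2, finite, unique ids) without changing `out`
  as_feature_matrix(out, label_col = label_col, id_col = id_col, min_classes = 1L)
  out
}

#' Write a samples-by-features matrix to CSV/TSV
#'
#' Doubles are written with full round-trip precision, so
#' `read_feature_matrix(write_feature_matrix(d, p))` reproduces finite values
#' bit-exactly.
#'
#' @param data Data frame with one label column and numeric feature columns.
#' @param path Output path; `.tsv` selects tab delimiting unless `delim` is given.
#' @param delim Field delimiter; `NULL` (default) as in [read_feature_matrix()].
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(data, path, delim = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::write_delim(data, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Write a feature-selection report to JSON
#'
#' Serializes an [mwmr_select()] or [kpls_mwmr()] result to a machine-readable
#' JSON report carrying the method name, `alpha`, `k`, the ordered selected
#' features with their weight / redundancy / criterion values, and a
#' provenance block (resolved configuration, seed and package version).
#'
#' @param selection An object of class `mwmr_selection` or `kpls_mwmr`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_selection_report()]
#' @export
write_selection_report <- function(selection, path) {
  report <- as_selection_report(selection)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a JSON selection report
#'
#' @param path Path written by [write_selection_report()].
#' @return A list with elements `method`, `alpha`, `k`, `selected` (tibble) and
#'   `provenance`.
#' @export
read_selection_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$selected <- tibble::as_tibble(rep$selected)
  rep$alpha <- as.numeric(rep$alpha)
  rep$k <- as.integer(rep$k)
  rep
}

as_selection_report <- function(selection) {
  if (inherits(selection, "kpls_mwmr")) selection <- selection$selection
  if (!inherits(selection, "mwmr_selection")) {
    abort("`selection` must be an mwmr_selection or kpls_mwmr object.")
  }
  trace <- selection$trace
  list(
    method = selection$method,
    alpha = selection$alpha,
    k = selection$k,
    selected = trace[c("feature", "weight", "redundancy", "criterion")],
    provenance = selection$provenance
  )
}

#' Write the ranked feature list as plain text
#'
#' One selected feature name per line, in selection order, for shell pipelines.
#'
#' @inheritParams write_selection_report
#' @return `path`, invisibly.
#' @export
write_feature_list <- function(selection, path) {
  report <- as_selection_report(selection)
  writeLines(report$selected$feature, path)
  invisible(path)
}
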