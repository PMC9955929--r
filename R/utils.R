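# Shared coercion and validation helpers. Every user-facing function takes a
# data frame with one label column; internally everything runs on a plain
# numeric matrix (samples x features) plus a factor of labels.

#' Split a data frame into a feature matrix and a label factor
#'
#' Validates and separates a samples-by-variables data frame into the numeric
#' feature matrix and the class-label vector used by every downstream
#' computation. Rows are never dropped and column order is preserved.
#'
#' @param data A data frame: one row per sample, numeric feature columns plus
#'   one categorical label column.
#' @param label_col Name of the label column (string). Default `"class"`.
#' @param id_col Optional name of a sample-identifier column; excluded from
#'   the features and carried as `sample_ids`.
#' @param min_classes Minimum number of distinct classes required (default 2;
#'   use 1 for label-free contexts).
#' @return A list with `x` (numeric matrix, `n x m`, named columns), `y`
#'   (factor of length `n`), `feature_names`, `sample_ids`, `classes` and
#'   `priors` (class frequencies, summing to 1).
#' @examples
#' d <- synth_benchmark(n_per_class = 5, n_noise = 2, seed = 1)
#' fm <- as_feature_matrix(d)
#' dim(fm$x)
#' @export
as_feature_matrix <- function(data, label_col = "class", id_col = NULL,
                              min_classes = 2L) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!label_col %in% names(data)) {
    abort(sprintf("label column '%s' not found in `data`.", label_col))
  }
  if (!is.null(id_col)) {
    if (!id_col %in% names(data)) {
      abort(sprintf("id column '%s' not found in `data`.", id_col))
    }
    sample_ids <- as.character(data[[id_col]])
    if (anyDuplicated(sample_ids)) abort("sample ids must be unique.")
  } else {
    sample_ids <- as.character(seq_len(nrow(data)))
  }
  feats <- setdiff(names(data), c(label_col, id_col))
  if (length(feats) < 1L) abort("`data` must contain at least one feature column.")
  if (anyDuplicated(feats)) {
    abort(sprintf("duplicate feature names: %s",
                  paste(unique(feats[duplicated(feats)]), collapse = ", ")))
  }
  for (f in feats) {
    if (!is.numeric(data[[f]])) {
      abort(sprintf("feature column '%s' is not numeric.", f))
    }
  }
  x <- as.matrix(data[feats])
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, , drop = TRUE]
    abort(sprintf("missing or non-finite value at row %d, feature '%s'; refusing to load.",
                  bad[["row"]], feats[bad[["col"]]]))
  }
  if (nrow(x) < 2L) abort("need at least 2 samples.")
  y <- data[[label_col]]
  if (anyNA(y)) abort(sprintf("missing values in label column '%s'.", label_col))
  y <- factor(y)
  if (nlevels(y) < min_classes) {
    abort(sprintf("need at least %d distinct classes, found %d.",
                  min_classes, nlevels(y)))
  }
  priors <- as.numeric(table(y)) / length(y)
  list(x = x, y = y, feature_names = feats, sample_ids = sample_ids,
       classes = levels(y), priors = setNames(priors, levels(y)))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  as.numeric(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, lower))
  }
  as.integer(x)
}

# min-max rescaling shared by the weighting and selection stages
#' Min-max normalize a numeric vector to [0, 1]
#'
#' `(w - min) / (max - min)`; an all-equal vector maps to all zeros so that
#' degenerate weight vectors cannot dominate the selection criterion.
#'
#' @param w Numeric vector.
#' @return Numeric vector of the same length in `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(w) {
  if (length(w) < 1L) abort("`w` must have length >= 1.")
  if (anyNA(w)) abort("`w` must not contain NA.")
  rng <- range(w)
  if (rng[1] == rng[2]) return(rep(0, length(w)))
  (w - rng[1]) / (rng[2] - rng[1])
}
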