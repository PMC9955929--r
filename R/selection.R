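# Pearson-correlation redundancy scoring and the alpha-weighted
# maximum-weight / minimum-redundancy (MWMR) greedy forward selection.
#
# Redundancy semantics: the greedy step can score a candidate's redundancy
# against the remaining candidate pool (`redundancy_target = "pool"`, the
# default, matching the algorithm's published pseudocode where
# r = R_score(f | S - F*)) or against the already-selected set ("selected",
# the mRMR-style reading). See the methods vignette for why both exist.

#' Sample Pearson correlation with a zero-variance convention
#'
#' Plain sample Pearson correlation, except that if either vector is constant
#' the correlation is defined as 0 (no association) instead of `NA`, so
#' constant features never poison a redundancy aggregate.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return A scalar in `[-1, 1]`.
#' @examples
#' pearson_r(1:5, -2 * (1:5) + 7)  # -1
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have the same length.")
  if (length(a) < 2L) abort("need at least 2 observations.")
  if (sd(a) == 0 || sd(b) == 0) return(0)
  as.numeric(cor(a, b))
}

#' Redundancy of a candidate feature against a feature set
#'
#' Aggregates the absolute Pearson correlations `|r(candidate, f)|` over the
#' columns of `selected` with the configured mode (`"mean"` default, `"max"`,
#' `"min"`). An empty set yields 0 (the first greedy pick carries no
#' redundancy penalty). Absolute correlation is used because redundancy is a
#' magnitude of association: an anti-correlated duplicate is just as
#' redundant.
#'
#' @param candidate Numeric vector of length `n`.
#' @param selected Numeric matrix (`n x s`) of feature columns, or `NULL` /
#'   zero-column matrix for the empty set.
#' @param aggregate One of `"mean"`, `"max"`, `"min"`.
#' @return A scalar in `[0, 1]`.
#' @export
redundancy_score <- function(candidate, selected, aggregate = c("mean", "max", "min")) {
  aggregate <- match.arg(aggregate)
  if (is.null(selected) || NCOL(selected) == 0L ||
      (is.matrix(selected) && ncol(selected) == 0L)) {
    return(0)
  }
  selected <- as.matrix(selected)
  if (nrow(selected) != length(candidate)) {
    abort("`candidate` and `selected` must have the same number of rows.")
  }
  r <- vapply(seq_len(ncol(selected)),
              function(j) abs(pearson_r(candidate, selected[, j])), numeric(1))
  switch(aggregate, mean = mean(r), max = max(r), min = min(r))
}

# |cor| matrix with zero-variance columns mapped to 0 and zero diagonal.
abs_cor_matrix <- function(x) {
  sds <- apply(x, 2, sd)
  C <- suppressWarnings(abs(cor(x)))
  C[is.na(C)] <- 0
  C[, sds == 0] <- 0
  C[sds == 0, ] <- 0
  diag(C) <- 0
  C
}

#' Greedy maximum-weight / minimum-redundancy feature selection
#'
#' Selects `k` features by greedy forward search. The first pick is the
#' feature with the largest (normalized) weight; every later step picks the
#' candidate maximizing the criterion
#' \deqn{R_j = \alpha \, w_j - (1 - \alpha) \, r_j}
#' where \eqn{w_j} is the candidate's weight and \eqn{r_j} its redundancy
#' score (aggregate of absolute Pearson correlations; see
#' [redundancy_score()]). At `alpha = 1` the order is exactly the descending
#' weight order; at `alpha = 0` (after the weight-driven first pick) only
#' redundancy matters. Ties break by higher raw weight, then lower column
#' index, so the result is deterministic across platforms.
#'
#' @param data Data frame holding the feature columns (a label column, if
#'   present, is ignored for redundancy but may sit in the frame).
#' @param weights A `feature_weights` tibble ([relieff_weights()],
#'   [fisher_weights()]) or a named numeric vector covering every feature.
#' @param alpha Weight factor in `[0, 1]` trading relevance against
#'   redundancy (default 0.3).
#' @param k Number of features to select (`1 <= k <= m`).
#' @param label_col Name of the label column to ignore if present
#'   (default `"class"`).
#' @param redundancy_target `"pool"` (default): a candidate's redundancy is
#'   aggregated over the *other remaining candidates*; `"selected"`: over the
#'   already-selected set (mRMR-style).
#' @param aggregate Redundancy aggregation mode, `"mean"` (default), `"max"`
#'   or `"min"`.
#' @param normalize_weights Use min-max normalized weights in the criterion
#'   (default `TRUE`) so weight and redundancy share the `[0, 1]` scale.
#' @param seed Optional integer recorded in the report provenance (selection
#'   itself is deterministic).
#' @return An object of class `mwmr_selection`: list with `features` (ordered
#'   character vector), `trace` (one tibble row per step: `step`, `pool_size`,
#'   `feature`, `weight`, `redundancy`, `criterion`), `alpha`, `k`, `method`,
#'   and `provenance`.
#' @examples
#' d <- synth_benchmark(n_per_class = 20, n_noise = 10, seed = 1)
#' w <- relieff_weights(d, k_neighbors = 5)
#' sel <- mwmr_select(d, w, alpha = 0.3, k = 3)
#' selected_features(sel)
#' @export
mwmr_select <- function(data, weights, alpha = 0.3, k,
                        label_col = "class",
                        redundancy_target = c("pool", "selected"),
                        aggregate = c("mean", "max", "min"),
                        normalize_weights = TRUE, seed = NULL) {
  redundancy_target <- match.arg(redundancy_target)
  aggregate <- match.arg(aggregate)
  alpha <- check_scalar(alpha, "alpha", lower = 0, upper = 1)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  feats <- setdiff(names(data), label_col)
  x <- as.matrix(data[feats])
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("missing values in feature columns.")
  m <- ncol(x)
  k <- check_count(k, "k")
  if (k > m) abort(sprintf("k = %d exceeds the number of features m = %d.", k, m))

  if (inherits(weights, "feature_weights") || is.data.frame(weights)) {
    wtab <- weights
    if (!all(c("feature", "weight") %in% names(wtab))) {
      abort("`weights` data frame must have columns 'feature' and 'weight'.")
    }
    w_raw <- setNames(wtab$weight, wtab$feature)
  } else if (is.numeric(weights) && !is.null(names(weights))) {
    w_raw <- weights
  } else {
    abort("`weights` must be a feature_weights tibble or a named numeric vector.")
  }
  if (!all(feats %in% names(w_raw))) {
    abort("`weights` must cover every feature column of `data`.")
  }
  w_raw <- as.numeric(w_raw[feats])
  w_use <- if (normalize_weights) minmax_normalize(w_raw) else w_raw

  C <- abs_cor_matrix(x)
  remaining <- seq_len(m)
  selected <- integer(0)
  trace <- vector("list", k)

  pick <- function(score, pool) {
    # argmax score, ties by higher raw weight then lower column index
    pool[order(-score, -w_raw[pool], pool)][1]
  }

  for (step in seq_len(k)) {
    if (step == 1L) {
      j <- pick(w_use[remaining], remaining)
      r_j <- 0
      crit <- alpha * w_use[j]
    } else {
      r <- switch(redundancy_target,
        selected = {
          sub <- C[remaining, selected, drop = FALSE]
          switch(aggregate,
                 mean = rowMeans(sub),
                 max = apply(sub, 1, max),
                 min = apply(sub, 1, min))
        },
        pool = {
          if (length(remaining) == 1L) {
            0
          } else {
            sub <- C[remaining, remaining, drop = FALSE]
            diag(sub) <- NA
            switch(aggregate,
                   mean = rowMeans(sub, na.rm = TRUE),
                   max = apply(sub, 1, max, na.rm = TRUE),
                   min = apply(sub, 1, min, na.rm = TRUE))
          }
        })
      crit_all <- alpha * w_use[remaining] - (1 - alpha) * r
      j <- pick(crit_all, remaining)
      at <- match(j, remaining)
      r_j <- if (length(r) == 1L) r else r[at]
      crit <- crit_all[at]
    }
    trace[[step]] <- tibble::tibble(
      step = step, pool_size = length(remaining), feature = feats[j],
      weight = w_use[j], raw_weight = w_raw[j],
      redundancy = as.numeric(r_j), criterion = as.numeric(crit)
    )
    selected <- c(selected, j)
    remaining <- setdiff(remaining, j)
  }

  trace <- dplyr::bind_rows(trace)
  structure(list(
    features = trace$feature,
    trace = trace,
    alpha = alpha,
    k = k,
    method = "mwmr",
    redundancy_target = redundancy_target,
    aggregate = aggregate,
    normalize_weights = normalize_weights,
    provenance = list(
      package = "kplsmwmr",
      version = as.character(utils::packageVersion("kplsmwmr")),
      alpha = alpha, k = k, redundancy_target = redundancy_target,
      aggregate = aggregate, normalize_weights = normalize_weights,
      n = nrow(x), m = m, seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  ), class = "mwmr_selection")
}

#' Extract the ordered selected feature names
#'
#' @param x An `mwmr_selection` or `kpls_mwmr` object.
#' @return Character vector of feature names in selection order.
#' @export
selected_features <- function(x) {
  if (inherits(x, "kpls_mwmr")) x <- x$selection
  if (!inherits(x, "mwmr_selection")) {
    abort("`x` must be an mwmr_selection or kpls_mwmr object.")
  }
  x$features
}

#' @export
print.mwmr_selection <- function(x, ...) {
  cat(sprintf("MWMR selection: k = %d, alpha = %.3g (redundancy: %s %s)\n",
              x$k, x$alpha, x$aggregate, x$redundancy_target))
  cat("  ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname mwmr_select
#' @param x,object An `mwmr_selection` object.
#' @param ... Unused.
#' @export
tidy.mwmr_selection <- function(x, ...) x$trace

#' @rdname mwmr_select
#' @export
glance.mwmr_selection <- function(x, ...) {
  tibble::tibble(method = x$method, alpha = x$alpha, k = x$k,
                 redundancy_target = x$redundancy_target,
                 aggregate = x$aggregate,
                 mean_redundancy = mean(x$trace$redundancy[-1]))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("in stage '%s': %s", stage, conditionMessage(e)))
  })
}

#' Run the full KPLS-MWMR feature-selection pipeline
#'
#' End-to-end composition: Gaussian Gram matrix (median-heuristic width by
#' default) -> kernel centering -> KPLS latent components -> rank-`p` latent
#' reconstruction -> ReliefF weighting of the reconstructed features ->
#' alpha-weighted maximum-weight / minimum-redundancy greedy selection over
#' the *original* feature columns. Deterministic given the configuration.
#'
#' @inheritParams fit_kpls
#' @inheritParams mwmr_select
#' @param k_neighbors ReliefF neighbors per class (default 10).
#' @return An object of class `kpls_mwmr`: list with `kpls` (the [fit_kpls()]
#'   model), `weights` (ReliefF weights of the reconstruction), `selection`
#'   (the [mwmr_select()] result) and `config`.
#' @examples
#' d <- synth_benchmark(n_per_class = 15, n_noise = 10, seed = 7)
#' fit <- kpls_mwmr(d, alpha = 0.3, k = 3, k_neighbors = 5)
#' selected_features(fit)
#' @export
kpls_mwmr <- function(data, label_col = "class", alpha = 0.3, k = 10,
                      width = "median", n_components = 10, k_neighbors = 10,
                      redundancy_target = c("pool", "selected"),
                      aggregate = c("mean", "max", "min"),
                      normalize_weights = TRUE, tol = 1e-8, max_iter = 500,
                      seed = NULL) {
  redundancy_target <- match.arg(redundancy_target)
  aggregate <- match.arg(aggregate)
  model <- with_stage("kpls", fit_kpls(data, label_col = label_col, width = width,
                                       n_components = n_components, tol = tol,
                                       max_iter = max_iter))
  recon <- with_stage("latent_reconstruct", latent_reconstruct(model))
  w <- with_stage("relieff", relieff_weights(recon, label_col = label_col,
                                             k_neighbors = k_neighbors))
  sel <- with_stage("mwmr_select", mwmr_select(
    data, w, alpha = alpha, k = k, label_col = label_col,
    redundancy_target = redundancy_target, aggregate = aggregate,
    normalize_weights = normalize_weights, seed = seed))
  sel$method <- "kpls-mwmr"
  sel$provenance <- c(sel$provenance, list(
    width = model$width, n_components = model$n_components,
    k_neighbors = k_neighbors, label_col = label_col
  ))
  structure(list(
    kpls = model,
    weights = w,
    selection = sel,
    features = sel$features,
    config = list(label_col = label_col, alpha = alpha, k = k,
                  width = model$width, n_components = model$n_components,
                  k_neighbors = k_neighbors,
                  redundancy_target = redundancy_target, aggregate = aggregate,
                  normalize_weights = normalize_weights, seed = seed)
  ), class = "kpls_mwmr")
}

#' @export
print.kpls_mwmr <- function(x, ...) {
  cat("KPLS-MWMR pipeline fit\n")
  print(x$kpls)
  print(x$selection)
  invisible(x)
}

#' @rdname kpls_mwmr
#' @param x,object A `kpls_mwmr` object.
#' @param ... Unused.
#' @export
tidy.kpls_mwmr <- function(x, ...) x$selection$trace

#' @rdname kpls_mwmr
#' @export
glance.kpls_mwmr <- function(x, ...) {
  dplyr::bind_cols(glance(x$kpls),
                   glance(x$selection)[c("alpha", "k", "redundancy_target",
                                         "aggregate", "mean_redundancy")])
}
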