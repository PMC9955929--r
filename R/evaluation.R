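# Repeated stratified k-fold cross-validation of a classifier on a selected
# feature subset, with accuracy, Cohen's kappa and macro-F1 computed per fold
# from its confusion matrix and then averaged (not pooled).

#' Confusion matrix with fixed class levels
#'
#' Rows are the true classes, columns the predicted classes, both over the
#' full class set (so absent classes appear as zero rows/columns).
#'
#' @param truth,estimate Factors or vectors of class labels.
#' @param classes Optional explicit class levels; default: union of levels.
#' @return A `q x q` integer matrix.
#' @export
confusion_matrix <- function(truth, estimate, classes = NULL) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length.")
  }
  if (is.null(classes)) {
    classes <- union(levels(factor(truth)), levels(factor(estimate)))
  }
  t_ <- factor(truth, levels = classes)
  e_ <- factor(estimate, levels = classes)
  unclass(table(truth = t_, predicted = e_))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `kappa = (p0 - pe) / (1 - pe)` with
#' `p0 = trace / N` the observed accuracy and
#' `pe = sum_i rowsum_i * colsum_i / N^2` the accuracy expected from the
#' marginals alone. The degenerate case `pe = 1` (all mass in a single cell)
#' is defined as 0 with a warning.
#'
#' @param confusion Square count matrix, rows = truth, columns = predicted.
#' @return A scalar `<= 1`.
#' @examples
#' cohens_kappa(matrix(c(40, 10, 10, 40), 2, byrow = TRUE))  # 0.6
#' @export
cohens_kappa <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) abort("`confusion` must be square.")
  N <- sum(cm)
  if (N < 1) abort("`confusion` must contain at least one count.")
  p0 <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (abs(1 - pe) < .Machine$double.eps) {
    warn("pe = 1 (degenerate marginals); kappa defined as 0.")
    return(0)
  }
  (p0 - pe) / (1 - pe)
}

#' Macro-averaged F1 score from a confusion matrix
#'
#' Per-class F1 is the harmonic mean of precision and recall taken from the
#' confusion matrix (defined as 0 when precision + recall = 0); the macro
#' score is their unweighted mean over classes, so every class counts equally
#' regardless of prevalence.
#'
#' @inheritParams cohens_kappa
#' @return A scalar in `[0, 1]`.
#' @export
macro_f1 <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) abort("`confusion` must be square.")
  if (sum(cm) < 1) abort("`confusion` must contain at least one count.")
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  mean(f1)
}

#' Linear SVM classifier contract
#'
#' The default base classifier of the evaluation harness: a linear-kernel
#' support vector machine with cost `C` (default 1), no feature scaling,
#' one-vs-one multiclass handling (as implemented by \pkg{e1071}). Any
#' classifier can be substituted by supplying a list with the same `fit(x, y)`
#' / `predict(model, x)` contract.
#'
#' @param cost Soft-margin cost parameter `C` (default 1).
#' @return A list with elements `fit`, `predict` and `label`.
#' @export
svm_linear <- function(cost = 1) {
  cost <- check_scalar(cost, "cost")
  if (cost <= 0) abort("`cost` must be > 0.")
  list(
    fit = function(x, y) e1071::svm(x = x, y = y, kernel = "linear",
                                    cost = cost, scale = FALSE),
    predict = function(model, x) predict(model, x),
    label = sprintf("linear SVM (C = %g)", cost)
  )
}

# Stratified fold assignment: per class, shuffle and deal round-robin, so
# class proportions per fold are within one sample of the global proportions.
stratified_folds <- function(y, n_folds, seed) {
  y <- factor(y)
  n <- length(y)
  sizes <- table(y)
  if (any(sizes < n_folds)) {
    abort(sprintf("class '%s' has %d members, fewer than n_folds = %d; use fewer folds.",
                  names(sizes)[which(sizes < n_folds)[1]],
                  min(sizes), n_folds))
  }
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Repeated stratified k-fold cross-validation on selected features
#'
#' Evaluates a classifier on a feature subset with `n_repeats` independent
#' stratified `n_folds`-fold partitions. Two selection modes:
#' `"select_once"` takes a fixed feature set (selected on the full data
#' beforehand) and only the classifier sees the fold structure;
#' `"within_fold"` re-runs a selector callback on each training split, so the
#' held-out rows never influence weighting or selection (the leakage-safe
#' protocol). Metrics (accuracy, Cohen's kappa, macro-F1) are computed per
#' fold from its confusion matrix and averaged.
#'
#' @param data Data frame: numeric features plus one label column.
#' @param label_col Name of the label column (default `"class"`).
#' @param features Character vector of feature names (required for
#'   `"select_once"` unless `selector` is given, in which case the selector is
#'   run once on the full data).
#' @param selector Function `function(train_data) -> character` returning
#'   feature names; required for `"within_fold"`.
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Number of repeats (default 10).
#' @param classifier A classifier contract as returned by [svm_linear()]
#'   (the default).
#' @param seed Integer seed; fold assignment for repeat `r` uses
#'   `seed + r - 1`, so the whole report is reproducible.
#' @param mode `"select_once"` or `"within_fold"`; default `"within_fold"`
#'   when a selector is supplied, else `"select_once"`.
#' @return An object of class `cv_eval`: list with `folds` (tibble: one row
#'   per repeat x fold with `accuracy`, `kappa`, `macro_f1` and the confusion
#'   matrix as a list column) and `config`. Use [glance()] for the aggregate
#'   means/sds and [tidy()] for the per-fold table.
#' @examples
#' d <- synth_benchmark(n_per_class = 20, n_noise = 5, seed = 1)
#' cv <- cross_validate(d, features = c("f1", "f2", "f3"),
#'                      n_folds = 5, n_repeats = 2, seed = 1)
#' glance(cv)
#' @export
cross_validate <- function(data, label_col = "class", features = NULL,
                           selector = NULL, n_folds = 10, n_repeats = 10,
                           classifier = svm_linear(), seed = 1,
                           mode = NULL) {
  fm <- as_feature_matrix(data, label_col)
  n_folds <- check_count(n_folds, "n_folds", lower = 2L)
  n_repeats <- check_count(n_repeats, "n_repeats")
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  if (is.null(mode)) {
    mode <- if (!is.null(selector)) "within_fold" else "select_once"
  }
  mode <- match.arg(mode, c("within_fold", "select_once"))
  if (mode == "within_fold" && !is.function(selector)) {
    abort("`within_fold` mode needs a selector callback (no fixed feature list can be leakage-safe).")
  }
  if (mode == "select_once" && is.null(features)) {
    if (!is.function(selector)) {
      abort("`select_once` mode needs `features` or a selector to run once on the full data.")
    }
    features <- selector(data)
  }
  if (!is.list(classifier) || !is.function(classifier$fit) || !is.function(classifier$predict)) {
    abort("`classifier` must provide fit(x, y) and predict(model, x).")
  }
  if (mode == "select_once") {
    if (length(features) < 1L) abort("`features` must be non-empty.")
    missing_f <- setdiff(features, fm$feature_names)
    if (length(missing_f) > 0L) {
      abort(sprintf("unknown feature(s): %s", paste(missing_f, collapse = ", ")))
    }
  }

  rows <- list()
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(fm$y, n_folds, seed = seed + r - 1L)
    for (f in seq_len(n_folds)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      feats <- if (mode == "within_fold") {
        selector(data[train_idx, , drop = FALSE])
      } else {
        features
      }
      if (length(feats) < 1L) abort("selector returned no features.")
      xtr <- fm$x[train_idx, feats, drop = FALSE]
      xte <- fm$x[test_idx, feats, drop = FALSE]
      ytr <- droplevels(fm$y[train_idx])
      if (nlevels(ytr) < length(fm$classes)) {
        abort(sprintf("training split of fold %d misses a class; use fewer folds.", f))
      }
      fit <- classifier$fit(xtr, factor(ytr, levels = fm$classes))
      pred <- classifier$predict(fit, xte)
      cm <- confusion_matrix(fm$y[test_idx], pred, classes = fm$classes)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_ = r, fold = f,
        accuracy = sum(diag(cm)) / sum(cm),
        kappa = cohens_kappa(cm),
        macro_f1 = macro_f1(cm),
        confusion = list(cm),
        features = list(feats)
      )
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  structure(list(
    folds = folds_tbl,
    config = list(label_col = label_col, n_folds = n_folds,
                  n_repeats = n_repeats, seed = seed, mode = mode,
                  classifier = classifier$label %||% "custom",
                  features = if (mode == "select_once") features else NULL)
  ), class = "cv_eval")
}

#' @export
print.cv_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Cross-validation (%d x %d-fold, %s, %s mode)\n",
              x$config$n_repeats, x$config$n_folds, x$config$classifier,
              x$config$mode))
  cat(sprintf("  accuracy %.4f +/- %.4f | kappa %.4f | macro-F1 %.4f\n",
              g$mean_accuracy, g$sd_accuracy, g$mean_kappa, g$mean_macro_f1))
  invisible(x)
}

#' @rdname cross_validate
#' @param x,object A `cv_eval` object.
#' @param ... Unused.
#' @export
tidy.cv_eval <- function(x, ...) {
  dplyr::select(x$folds, "repeat_", "fold", "accuracy", "kappa", "macro_f1")
}

#' @rdname cross_validate
#' @export
glance.cv_eval <- function(x, ...) {
  f <- x$folds
  tibble::tibble(
    n_folds = x$config$n_folds, n_repeats = x$config$n_repeats,
    mean_accuracy = mean(f$accuracy), sd_accuracy = sd(f$accuracy),
    mean_kappa = mean(f$kappa), sd_kappa = sd(f$kappa),
    mean_macro_f1 = mean(f$macro_f1), sd_macro_f1 = sd(f$macro_f1)
  )
}

#' Sweep the weight factor alpha and cross-validate each selection
#'
#' Runs the full KPLS-MWMR pipeline at every `alpha`, evaluates the selected
#' `k` features with repeated stratified cross-validation, and tabulates the
#' mean accuracy per `alpha`. The selection is recomputed per alpha; the fold
#' structure is identical across alphas (same seed), so differences reflect
#' the selections only.
#'
#' @inheritParams kpls_mwmr
#' @inheritParams cross_validate
#' @param alphas Numeric vector of weight factors in `[0, 1]`
#'   (default `seq(0.1, 0.9, by = 0.1)`).
#' @param k Number of features selected per alpha (default 3).
#' @param selection_mode `"select_once"` (default; selection on the full data,
#'   matching how the benchmark tabulates per-alpha accuracies) or
#'   `"within_fold"` (leakage-safe re-selection per training split).
#' @param ... Further arguments passed to [kpls_mwmr()].
#' @return A tibble of class `alpha_sweep`, sorted by alpha, with columns
#'   `alpha`, `mean_accuracy`, `sd_accuracy`, `mean_kappa`, `mean_macro_f1`
#'   and `features` (list column of the selected names).
#' @export
alpha_sweep <- function(data, label_col = "class",
                        alphas = seq(0.1, 0.9, by = 0.1), k = 3,
                        n_folds = 10, n_repeats = 10,
                        classifier = svm_linear(), seed = 1,
                        selection_mode = c("select_once", "within_fold"),
                        ...) {
  selection_mode <- match.arg(selection_mode)
  if (!is.numeric(alphas) || length(alphas) < 1L ||
      any(alphas < 0 | alphas > 1)) {
    abort("`alphas` must be numeric values in [0, 1].")
  }
  rows <- purrr::map(sort(alphas), function(a) {
    if (selection_mode == "select_once") {
      fit <- kpls_mwmr(data, label_col = label_col, alpha = a, k = k, ...)
      cv <- cross_validate(data, label_col = label_col,
                           features = selected_features(fit),
                           n_folds = n_folds, n_repeats = n_repeats,
                           classifier = classifier, seed = seed,
                           mode = "select_once")
      feats <- selected_features(fit)
    } else {
      sel_fun <- function(train) {
        selected_features(kpls_mwmr(train, label_col = label_col,
                                    alpha = a, k = k, ...))
      }
      cv <- cross_validate(data, label_col = label_col, selector = sel_fun,
                           n_folds = n_folds, n_repeats = n_repeats,
                           classifier = classifier, seed = seed,
                           mode = "within_fold")
      feats <- NA_character_
    }
    g <- glance(cv)
    tibble::tibble(alpha = a, mean_accuracy = g$mean_accuracy,
                   sd_accuracy = g$sd_accuracy, mean_kappa = g$mean_kappa,
                   mean_macro_f1 = g$mean_macro_f1, features = list(feats))
  })
  tibble::new_tibble(dplyr::bind_rows(rows), class = "alpha_sweep")
}
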