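# Kernel partial least squares on a Gaussian Gram matrix. The latent scores
# maximize covariance between the kernel-mapped inputs and a centered one-hot
# label indicator; the rank-p reconstruction restores the original feature
# dimensionality so downstream per-feature weighting stays aligned with the
# input columns.

#' Gaussian kernel Gram matrix
#'
#' `K[i, j] = exp(-||x_i - x_j||^2 / s)`: symmetric, unit diagonal, entries in
#' (0, 1]. Note the width `s` divides the *squared* Euclidean distance.
#'
#' @param x Numeric matrix, samples in rows.
#' @param width Kernel width `s` (> 0).
#' @return An `n x n` symmetric matrix with unit diagonal.
#' @examples
#' x <- matrix(rnorm(15), 5, 3)
#' K <- gaussian_gram(x, width = median_width(x))
#' @export
gaussian_gram <- function(x, width) {
  x <- as.matrix(x)
  width <- check_scalar(width, "width")
  if (width <= 0) abort("`width` must be > 0.")
  d2 <- as.matrix(dist(x))^2
  K <- exp(-d2 / width)
  diag(K) <- 1
  dimnames(K) <- NULL
  K
}

#' Median-heuristic kernel width
#'
#' The median of all `n(n-1)/2` pairwise squared Euclidean distances: a
#' deterministic default width for [gaussian_gram()] when no tuning rule is
#' available. Zero-distance pairs (duplicated rows) are included in the median.
#'
#' @param x Numeric matrix, samples in rows (`n >= 2`).
#' @return A positive scalar.
#' @export
median_width <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort("need at least 2 samples.")
  d2 <- as.numeric(dist(x))^2
  w <- median(d2)
  if (w <= 0) abort("all pairwise distances are zero; kernel width degenerate.")
  w
}

#' Double-center a Gram matrix
#'
#' Returns `(I - J/n) K (I - J/n)` with `J` the all-ones matrix: the Gram
#' matrix of the feature-space points after subtracting their mean. Row and
#' column sums of the result are zero (to numerical precision).
#'
#' @param K Square symmetric matrix.
#' @return The centered matrix, same shape.
#' @export
center_gram <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) abort("`K` must be square.")
  n <- nrow(K)
  rm_ <- rowMeans(K)
  gm <- mean(K)
  # (I - J/n) K (I - J/n) expanded; avoids forming J
  K - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
}

# Core NIPALS-style iteration on a centered Gram matrix and a centered label
# indicator. Deterministic: u starts at the first (non-degenerate) column of
# the current deflated Y. Deflation K <- (I - t t') K (I - t t'),
# Y <- Y - t t' Y keeps successive scores orthonormal.
kpls_fit_gram <- function(Kc, Yc, n_components, tol = 1e-8, max_iter = 500L) {
  n <- nrow(Kc)
  K <- Kc
  Y <- Yc
  k0 <- norm(Kc, "F")
  scores <- matrix(0, n, 0)
  converged <- logical(0)
  for (comp in seq_len(n_components)) {
    if (norm(K, "F") < max(tol, 1e-10 * k0)) {
      warn(sprintf("Gram matrix numerically exhausted after %d components; requested %d.",
                   comp - 1L, n_components))
      break
    }
    if (norm(Y, "F") < 1e-10) {
      warn(sprintf("label space exhausted after %d components; requested %d.",
                   comp - 1L, n_components))
      break
    }
    u <- Y[, 1]
    if (sqrt(sum(u^2)) < 1e-12) u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(0, n)
    ok <- FALSE
    tt <- NULL
    for (it in seq_len(max_iter)) {
      tt <- as.numeric(K %*% u)
      nt <- sqrt(sum(tt^2))
      if (nt < 1e-300) break
      tt <- tt / nt
      cv <- as.numeric(crossprod(Y, tt))
      u <- as.numeric(Y %*% cv)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-300) break
      u <- u / nu
      if (sqrt(sum((tt - t_old)^2)) < tol) {
        ok <- TRUE
        break
      }
      t_old <- tt
    }
    if (is.null(tt) || sqrt(sum(tt^2)) == 0) {
      warn(sprintf("degenerate direction at component %d; stopping at %d components.",
                   comp, comp - 1L))
      break
    }
    if (!ok) {
      warn(sprintf("component %d did not converge within %d iterations; accepting current score.",
                   comp, max_iter))
    }
    scores <- cbind(scores, tt)
    converged <- c(converged, ok)
    tK <- crossprod(tt, K)
    K <- K - tt %*% tK
    K <- K - (K %*% tt) %*% t(tt)
    Y <- Y - tt %*% crossprod(tt, Y)
  }
  colnames(scores) <- if (ncol(scores) > 0) paste0("t", seq_len(ncol(scores))) else NULL
  list(scores = scores, converged = converged, residual_gram = K, residual_y = Y)
}

#' Fit kernel PLS latent components
#'
#' Builds the Gaussian Gram matrix of the feature columns, double-centers it,
#' encodes the class labels as a centered one-hot indicator, and extracts up
#' to `n_components` orthonormal latent score vectors by the iterative KPLS
#' algorithm (each component maximizes covariance between the kernel-mapped
#' inputs and the label indicator, followed by deflation of both). The fitted
#' object also carries the rank-`p` latent reconstruction of the feature
#' matrix, `T T' X_c + column means`, which has the same columns as the input
#' and is what downstream feature weighting consumes.
#'
#' @param data Data frame: numeric feature columns plus one label column.
#' @param label_col Name of the label column (default `"class"`).
#' @param width Kernel width `s` (> 0), or `"median"` (default) for the
#'   median heuristic of [median_width()].
#' @param n_components Number of latent components `p` (default 10); clipped
#'   to `n - 1` (and to the numerical rank of the centered Gram matrix) with
#'   a warning.
#' @param tol Convergence tolerance on the change of the score vector
#'   (default 1e-8).
#' @param max_iter Iteration cap per component (default 500).
#' @return An object of class `kpls`: a list with `scores` (`n x p`,
#'   orthonormal columns), `gram`, `gram_centered`, `y_indicator`,
#'   `reconstruction` (`n x m` matrix), `column_means`, `width`, and metadata.
#' @examples
#' d <- synth_benchmark(n_per_class = 10, n_noise = 5, seed = 1)
#' fit <- fit_kpls(d, n_components = 2)
#' crossprod(fit$scores)  # ~ identity
#' @export
fit_kpls <- function(data, label_col = "class", width = "median",
                     n_components = 10, tol = 1e-8, max_iter = 500) {
  fm <- as_feature_matrix(data, label_col)
  n <- nrow(fm$x)
  n_components <- check_count(n_components, "n_components", lower = 0L)
  tol <- check_scalar(tol, "tol", lower = 0)
  max_iter <- check_count(max_iter, "max_iter")
  if (identical(width, "median")) width <- median_width(fm$x)
  width <- check_scalar(width, "width")
  if (width <= 0) abort("`width` must be > 0.")
  if (n_components > n - 1L) {
    warn(sprintf("n_components clipped from %d to n - 1 = %d.", n_components, n - 1L))
    n_components <- n - 1L
  }

  K <- gaussian_gram(fm$x, width)
  Kc <- center_gram(K)
  ind <- stats::model.matrix(~ y - 1, data = data.frame(y = fm$y))
  colnames(ind) <- fm$classes
  Yc <- scale(ind, center = TRUE, scale = FALSE)
  fit <- kpls_fit_gram(Kc, Yc, n_components, tol = tol, max_iter = max_iter)

  col_means <- colMeans(fm$x)
  xc <- sweep(fm$x, 2, col_means)
  Tm <- fit$scores
  recon <- if (ncol(Tm) > 0) Tm %*% crossprod(Tm, xc) else matrix(0, n, ncol(xc))
  recon <- sweep(recon, 2, col_means, "+")
  colnames(recon) <- fm$feature_names

  structure(list(
    scores = Tm,
    gram = K,
    gram_centered = Kc,
    y_indicator = Yc,
    reconstruction = recon,
    column_means = col_means,
    x = fm$x,
    y = fm$y,
    width = width,
    n_components = ncol(Tm),
    converged = fit$converged,
    label_col = label_col,
    feature_names = fm$feature_names,
    classes = fm$classes
  ), class = "kpls")
}

#' Latent reconstruction of the feature matrix
#'
#' Projects the column-centered feature matrix onto the fitted latent score
#' space and adds the column means back: `T T' X_c + means`. With
#' `n_components = 0` this is the column-means matrix; when the scores span
#' the column space of the centered data it reproduces the input exactly.
#'
#' @param model A fitted [fit_kpls()] object.
#' @param n_components Use only the first `n_components` scores (default: all
#'   fitted components).
#' @return A tibble: the label column followed by the reconstructed feature
#'   columns (same names and order as the input features).
#' @export
latent_reconstruct <- function(model, n_components = NULL) {
  if (!inherits(model, "kpls")) abort("`model` must be a fitted kpls object.")
  if (is.null(n_components)) {
    recon <- model$reconstruction
  } else {
    n_components <- check_count(n_components, "n_components", lower = 0L)
    if (n_components > model$n_components) {
      abort(sprintf("only %d components fitted.", model$n_components))
    }
    Tm <- model$scores[, seq_len(n_components), drop = FALSE]
    xc <- sweep(model$x, 2, model$column_means)
    recon <- if (n_components > 0) Tm %*% crossprod(Tm, xc) else matrix(0, nrow(xc), ncol(xc))
    recon <- sweep(recon, 2, model$column_means, "+")
    colnames(recon) <- model$feature_names
  }
  out <- tibble::as_tibble(recon)
  out[[model$label_col]] <- model$y
  dplyr::relocate(out, !!rlang::sym(model$label_col))
}

#' @export
print.kpls <- function(x, ...) {
  cat(sprintf("Kernel PLS fit: %d samples, %d features, %d classes\n",
              nrow(x$x), ncol(x$x), length(x$classes)))
  cat(sprintf("  components: %d (converged: %d)  kernel width s = %.6g\n",
              x$n_components, sum(x$converged), x$width))
  invisible(x)
}

#' @rdname fit_kpls
#' @param x,object A `kpls` object.
#' @param ... Unused.
#' @export
tidy.kpls <- function(x, ...) {
  out <- tibble::as_tibble(x$scores)
  out[[x$label_col]] <- x$y
  dplyr::relocate(out, !!rlang::sym(x$label_col))
}

#' @rdname fit_kpls
#' @export
glance.kpls <- function(x, ...) {
  xc <- sweep(x$x, 2, x$column_means)
  rec <- sweep(x$reconstruction, 2, x$column_means)
  tibble::tibble(
    n = nrow(x$x), m = ncol(x$x), q = length(x$classes),
    n_components = x$n_components, width = x$width,
    prop_var_captured = if (sum(xc^2) > 0) sum(rec^2) / sum(xc^2) else NA_real_
  )
}
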