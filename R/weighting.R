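# Per-feature relevance weighting. ReliefF is the weighting stage of the
# selection pipeline; the Fisher score is the filter baseline it is compared
# against. Both return the same tibble shape so they are interchangeable
# upstream of the greedy selection.

# Kononenko's ReliefF over all n instances (no subsampling). Distances are
# Manhattan on range-normalized features; diff(f, a, b) = |a_f - b_f| / range_f,
# so a constant feature contributes exactly 0. Miss contributions are weighted
# by P(class_miss) / (1 - P(class(x))). Neighbor ties break by ascending
# sample index.
relieff_core <- function(x, y, k_neighbors = 10L) {
  n <- nrow(x)
  m <- ncol(x)
  y <- factor(y)
  sizes <- table(y)
  if (any(sizes < 2L)) {
    abort(sprintf("class '%s' has fewer than 2 members; ReliefF needs k >= 1 same-class neighbors.",
                  names(sizes)[which(sizes < 2L)[1]]))
  }
  k <- check_count(k_neighbors, "k_neighbors")
  kmax <- min(sizes) - 1L
  if (k > kmax) {
    warn(sprintf("k_neighbors clipped from %d to min class size - 1 = %d.", k, kmax))
    k <- kmax
  }
  rng <- apply(x, 2, range)
  denom <- rng[2, ] - rng[1, ]
  scale_ <- ifelse(denom > 0, 1 / denom, 0)   # constant features drop out
  xs <- sweep(x, 2, scale_, "*")
  D <- as.matrix(dist(xs, method = "manhattan"))
  priors <- as.numeric(sizes) / n
  names(priors) <- names(sizes)
  by_class <- split(seq_len(n), y)
  classes <- levels(y)

  W <- numeric(m)
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    for (cl in classes) {
      pool <- by_class[[cl]]
      if (cl == ci) pool <- pool[pool != i]
      nb <- pool[order(D[i, pool], pool)][seq_len(k)]
      diffs <- colSums(abs(sweep(xs[nb, , drop = FALSE], 2, xs[i, ])))
      if (cl == ci) {
        W <- W - diffs / (n * k)
      } else {
        W <- W + (priors[[cl]] / (1 - priors[[ci]])) * diffs / (n * k)
      }
    }
  }
  W
}

weights_tibble <- function(w, feature_names, method, normalize = TRUE) {
  w <- unname(as.numeric(w))
  tibble::new_tibble(
    tibble::tibble(
      feature = feature_names,
      weight = as.numeric(w),
      normalized = minmax_normalize(as.numeric(w)),
      rank = as.integer(rank(-w, ties.method = "first"))
    ),
    method = method, class = "feature_weights"
  )
}

#' ReliefF feature weights
#'
#' Computes Kononenko's multiclass ReliefF weight for every feature column:
#' each instance in turn contributes the range-normalized differences to its
#' `k_neighbors` nearest same-class neighbors (hits, subtracted) and, per
#' other class, its `k_neighbors` nearest neighbors of that class (misses,
#' added with prior weighting `P(c)/(1 - P(class(x)))`). All `n` instances
#' are used deterministically — no random subsampling — so the result is a
#' pure function of the data. Weights lie in `[-1, 1]`; a feature unrelated
#' to the class labels scores near 0.
#'
#' @param data Data frame: numeric features plus one label column. Pass the
#'   output of [latent_reconstruct()] to weight the KPLS-filtered matrix.
#' @param label_col Name of the label column (default `"class"`).
#' @param k_neighbors Number of hit/miss neighbors per class (default 10);
#'   clipped to the smallest class size minus one, with a warning.
#' @return A `feature_weights` tibble with columns `feature`, `weight`,
#'   `normalized` (min-max rescaled to `[0, 1]`) and `rank` (1 = largest
#'   weight, ties broken by column order).
#' @examples
#' d <- synth_benchmark(n_per_class = 20, n_noise = 10, seed = 1)
#' relieff_weights(d, k_neighbors = 5)
#' @export
relieff_weights <- function(data, label_col = "class", k_neighbors = 10) {
  fm <- as_feature_matrix(data, label_col)
  w <- relieff_core(fm$x, fm$y, k_neighbors)
  weights_tibble(w, fm$feature_names, method = "relieff")
}

#' Fisher score feature weights
#'
#' The classical supervised filter score
#' \deqn{F(f) = \frac{\sum_c n_c (\mu_{cf} - \mu_f)^2}{\sum_c n_c \sigma_{cf}^2}}
#' (between-class scatter over within-class scatter, class variances taken as
#' population variances). A feature whose class means coincide scores 0. A
#' feature with zero within-class variance in every class but distinct means
#' has an infinite ratio; it is mapped just above the largest finite score so
#' it ranks first without propagating `Inf`.
#'
#' @inheritParams relieff_weights
#' @return A `feature_weights` tibble (see [relieff_weights()]).
#' @export
fisher_weights <- function(data, label_col = "class") {
  fm <- as_feature_matrix(data, label_col)
  sizes <- table(fm$y)
  if (any(sizes < 2L)) {
    abort(sprintf("class '%s' has fewer than 2 members.",
                  names(sizes)[which(sizes < 2L)[1]]))
  }
  mu <- colMeans(fm$x)
  num <- numeric(ncol(fm$x))
  den <- numeric(ncol(fm$x))
  for (cl in levels(fm$y)) {
    rows <- fm$y == cl
    nc <- sum(rows)
    muc <- colMeans(fm$x[rows, , drop = FALSE])
    varc <- colMeans(sweep(fm$x[rows, , drop = FALSE], 2, muc)^2)
    num <- num + nc * (muc - mu)^2
    den <- den + nc * varc
  }
  w <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  if (any(is.infinite(w))) {
    top <- if (any(is.finite(w) & w > 0)) max(w[is.finite(w)]) else 1
    w[is.infinite(w)] <- top + 1
  }
  weights_tibble(w, fm$feature_names, method = "fisher")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("Feature weights (%s), %d features\n", attr(x, "method"), nrow(x)))
  NextMethod()
}
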