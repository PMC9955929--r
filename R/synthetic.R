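#' Generate the three-class synthetic benchmark dataset
#'
#' Builds the synthetic classification benchmark used throughout the package's
#' tests and examples: three balanced classes whose informative features are
#' drawn from well-separated Gaussians \eqn{N(5,1)}, \eqn{N(10,1)} and
#' \eqn{N(15,1)} (one distribution per class, shared by all informative
#' features), plus a block of pure-noise features drawn i.i.d. from
#' \eqn{N(0, 0.01)} (variance 0.01) independently of the class. The defaults
#' produce a 300 x 103 matrix (100 samples per class, 3 informative + 100
#' noise features).
#'
#' Columns are filled in a fixed order (informative features first, one full
#' column at a time in class-block order, then noise columns) so a given seed
#' always yields a bit-identical dataset.
#'
#' @param n_per_class Samples per class (default 100).
#' @param class_means Numeric vector of per-class means for the informative
#'   features (default `c(5, 10, 15)`); its length sets the number of classes.
#' @param class_sd Standard deviation of the informative features within each
#'   class (default 1).
#' @param n_informative Number of informative features, named `f1..` (default 3).
#' @param n_noise Number of label-independent noise features (default 100).
#' @param noise_var Variance of the noise features (default 0.01, i.e. sd 0.1);
#'   interpreted as the second parameter of the conventional `N(mu, sigma^2)`
#'   notation.
#' @param seed Integer seed; required for reproducibility (default 1).
#' @return A tibble with a `class` factor column (`"c1"`, `"c2"`, ...) followed
#'   by feature columns `f1 .. f{n_informative + n_noise}`.
#' @examples
#' d <- synth_benchmark(seed = 42)
#' dim(d)        # 300 rows, 1 label + 103 features
#' table(d$class)
#' @export
synth_benchmark <- function(n_per_class = 100, class_means = c(5, 10, 15),
                            class_sd = 1, n_informative = 3, n_noise = 100,
                            noise_var = 0.01, seed = 1) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  if (!is.numeric(class_means) || length(class_means) < 2L || anyNA(class_means)) {
    abort("`class_means` must be a numeric vector with >= 2 class means.")
  }
  class_sd <- check_scalar(class_sd, "class_sd", lower = 0)
  if (class_sd <= 0) abort("`class_sd` must be > 0.")
  n_informative <- check_count(n_informative, "n_informative")
  n_noise <- check_count(n_noise, "n_noise", lower = 0L)
  noise_var <- check_scalar(noise_var, "noise_var", lower = 0)
  if (noise_var <= 0) abort("`noise_var` must be > 0.")
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)

  q <- length(class_means)
  n <- q * n_per_class
  m <- n_informative + n_noise
  labels <- factor(rep(paste0("c", seq_len(q)), each = n_per_class))

  x <- withr::with_seed(seed, {
    out <- matrix(0, n, m)
    for (j in seq_len(n_informative)) {
      for (cc in seq_len(q)) {
        rows <- (cc - 1L) * n_per_class + seq_len(n_per_class)
        out[rows, j] <- rnorm(n_per_class, class_means[cc], class_sd)
      }
    }
    for (j in seq_len(n_noise)) {
      out[, n_informative + j] <- rnorm(n, 0, sqrt(noise_var))
    }
    out
  })
  colnames(x) <- paste0("f", seq_len(m))
  dplyr::bind_cols(tibble::tibble(class = labels), tibble::as_tibble(x))
}
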