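# ggplot2 autoplot() methods, one per result type.

#' @rdname relieff_weights
#' @param object A `feature_weights` tibble.
#' @param top_n Number of top-ranked features to show (default 20).
#' @param ... Unused.
#' @export
autoplot.feature_weights <- function(object, top_n = 20, ...) {
  d <- dplyr::slice_min(object, .data$rank, n = top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature, .data$weight),
                                  y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("%s weight", attr(object, "method")),
                  title = "Top feature weights")
}

#' @rdname mwmr_select
#' @export
autoplot.mwmr_selection <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$trace[c("step", "weight", "redundancy", "criterion")],
    cols = c("weight", "redundancy", "criterion"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$step, .data$value,
                                  colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$trace$step,
                                labels = object$trace$feature) +
    ggplot2::labs(x = "selection step", y = "value",
                  title = sprintf("MWMR greedy trace (alpha = %.2g)", object$alpha)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname fit_kpls
#' @export
autoplot.kpls <- function(object, ...) {
  if (object$n_components < 2L) {
    abort("need at least 2 fitted components to plot scores.")
  }
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$t1, .data$t2,
                                  colour = !!rlang::sym(object$label_col))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = "KPLS latent scores",
                  x = "component 1", y = "component 2")
}

#' @rdname kpls_mwmr
#' @export
autoplot.kpls_mwmr <- function(object, ...) {
  autoplot(object$selection, ...)
}

#' @rdname cross_validate
#' @export
autoplot.cv_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(tidy(object),
                           cols = c("accuracy", "kappa", "macro_f1"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = "Cross-validated classification metrics")
}

#' @rdname alpha_sweep
#' @param object An `alpha_sweep` tibble.
#' @export
autoplot.alpha_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$alpha, .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                                        ymax = .data$mean_accuracy + .data$sd_accuracy),
                           width = 0.02) +
    ggplot2::labs(x = expression(alpha), y = "mean CV accuracy",
                  title = "Accuracy across the weight factor")
}
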