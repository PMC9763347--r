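#' Plot a wavelet spectrum
#'
#' Log2 level energies against level index, optionally with the fitted
#' spectral slope line.
#'
#' @param object A `wavelet_spectrum`.
#' @param fit Optional `slope_fit` to overlay.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot wavelet_spectrum
#' @export
autoplot.wavelet_spectrum <- function(object, fit = NULL, ...) {
  est <- attr(object, "estimator")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$level, y = .data$log2_energy)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::labs(
      x = "level j", y = expression(S(j) == log[2] ~ energy),
      title = sprintf("Wavelet spectrum (%s, %s)",
                      attr(object, "wavelet"), est$kind)
    )
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept,
                                  colour = "red") +
      ggplot2::labs(subtitle = sprintf("slope = %.3f, H = %.3f",
                                       fit$slope, fit$hurst))
  }
  p
}

#' Plot a contamination experiment
#'
#' Boxplots of the Hurst estimates per energy estimator with the theoretical
#' value marked.
#'
#' @param object A `contamination_experiment`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot contamination_experiment
#' @export
autoplot.contamination_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(object$results,
                              c("h_variance", "h_distance_variance"),
                              names_to = "estimator", names_prefix = "h_",
                              values_to = "h")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimator, y = .data$h)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$params$h_true,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "estimated H",
                  title = "Hurst estimates under coefficient contamination")
}

#' Plot an evaluation's ROC curve(s)
#'
#' Draws the ROC staircase stored for probability-producing models
#' (logistic regression).
#'
#' @param object A `pw_evaluation` from [evaluate_models()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot pw_evaluation
#' @export
autoplot.pw_evaluation <- function(object, ...) {
  rocs <- purrr::map2(object$roc, object$model, function(rc, m) {
    if (is.null(rc)) NULL else dplyr::mutate(rc, model = m)
  })
  rocs <- dplyr::bind_rows(rocs)
  if (nrow(rocs) == 0) {
    abort("No ROC curves stored (only label-producing models evaluated).",
          class = "pw_domain_error")
  }
  ggplot2::ggplot(rocs, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                     colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = "ROC curve (test partition)")
}
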