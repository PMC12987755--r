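#' Plot an evaluation table
#'
#' Bar chart of bias or relative RMSE per estimator, faceted by condition and
#' parameter, with the satisfactory-performance threshold drawn as a dashed
#' line.
#'
#' @param object an `ipd_evaluation` from [evaluate_estimates()].
#' @param metric `"bias"` or `"rel_rmse"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ipd_evaluation <- function(object, metric = c("bias", "rel_rmse"),
                                    ...) {
  metric <- match.arg(metric)
  hline <- if (metric == "bias") c(-0.015, 0.015) else 125
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data[[metric]])) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = hline, linetype = "dashed") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$parameter),
                        cols = ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = NULL, y = if (metric == "bias") "bias"
                  else "relative RMSE (reference = 100)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot detection statistics
#'
#' Per-item drift statistics against the flagging threshold, colored by flag
#' status; iterations of the iterative approach are faceted.
#'
#' @param object an `ipd_partition` from [detect_drift()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ipd_partition <- function(object, ...) {
  ggplot2::ggplot(object$stats,
                  ggplot2::aes(x = .data$item, y = .data$value,
                               color = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$iteration), labeller = "label_both") +
    ggplot2::labs(x = NULL, y = object$config$statistic) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot estimated drift effects
#'
#' Bars of the estimated per-item drift effects from a regularized fit, with
#' the selection threshold marked.
#'
#' @param object an `ipd_reg_fit` from [fit_regularized()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ipd_reg_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$delta,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$zero_tol,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "estimated drift effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
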