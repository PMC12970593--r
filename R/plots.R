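#' Plot training curves
#'
#' Loss components and validation metrics per epoch, faceted.
#'
#' @param object A `spin_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spin_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$log,
    cols = c("l_class", "l_span", "l_total", "val_f1_mw", "val_acc_w"),
    names_to = "series", values_to = "value"
  )
  long$panel <- ifelse(grepl("^val_", long$series), "validation metric", "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 1) +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training trajectory",
                  subtitle = "dotted line: selected checkpoint") +
    ggplot2::theme_minimal()
}

#' Plot per-class F1 from an evaluation report
#'
#' @param object A `spin_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spin_metrics <- function(object, ...) {
  ggplot2::ggplot(object$per_class,
                  ggplot2::aes(x = .data$class, y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$f1_mw, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "per-class F1",
                  title = "Per-class F1",
                  subtitle = sprintf("dashed line: macro-weighted F1 = %.3f",
                                     object$f1_mw)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot paired confidence distributions with the suggested threshold
#'
#' @param object A `spin_confidence_split` from
#'   [confidence_distributions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spin_confidence_split <- function(object, ...) {
  long <- tidyr::pivot_longer(object$histogram,
                              cols = c("density_in", "density_out"),
                              names_to = "set", values_to = "density")
  long$set <- ifelse(long$set == "density_in", "in-family", "out-of-family")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_mid,
                                          y = .data$density,
                                          fill = .data$set)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "top-class confidence", y = "density", fill = NULL,
                  title = "Confidence separation") +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold,
                                 linetype = "dashed")
  }
  p
}
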