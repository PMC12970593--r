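#' Tidy a fitted model's training log
#'
#' @param x A `spin_fit`.
#' @param ... Unused.
#' @return The per-epoch training log as a tibble (`epoch`, loss
#'   components, validation metrics, learning rate).
#' @export
tidy.spin_fit <- function(x, ...) x$log

#' One-row summary of a fitted model
#'
#' @param x A `spin_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the class count, span-predictor flag,
#'   best epoch, its validation metrics, seed, and temperature.
#' @export
glance.spin_fit <- function(x, ...) {
  row <- x$log[x$best_epoch, ]
  tibble(
    n_classes = x$config$n_classes,
    use_span_predictor = x$config$use_span_predictor,
    best_epoch = x$best_epoch,
    val_f1_mw = row$val_f1_mw,
    val_acc_w = row$val_acc_w,
    seed = x$seed,
    temperature = x$temperature %||% NA_real_
  )
}

#' Tidy an evaluation report
#'
#' @param x A `spin_metrics` object from [spin_evaluate()].
#' @param ... Unused.
#' @return A long tibble of metrics: the two aggregate metrics, one
#'   per-class F1 row per class, and — when spans were evaluated — one
#'   row per boundary with its bootstrap interval.
#' @export
tidy.spin_metrics <- function(x, ...) {
  rows <- tibble(
    metric = c("weighted_accuracy", "macro_weighted_f1"),
    class = NA_character_,
    value = c(x$acc_w, x$f1_mw),
    ci_low = NA_real_, ci_high = NA_real_
  )
  rows <- dplyr::bind_rows(rows, tibble(
    metric = "f1", class = x$per_class$class, value = x$per_class$f1,
    ci_low = NA_real_, ci_high = NA_real_
  ))
  if (!is.null(x$span)) {
    rows <- dplyr::bind_rows(rows, tibble(
      metric = paste0("span_", x$span$boundary, "_accuracy"),
      class = NA_character_,
      value = x$span$accuracy,
      ci_low = if ("ci_low" %in% names(x$span)) x$span$ci_low else NA_real_,
      ci_high = if ("ci_high" %in% names(x$span)) x$span$ci_high else NA_real_
    ))
  }
  rows
}

#' One-row summary of an evaluation report
#'
#' @param x A `spin_metrics`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, the aggregate metrics, and span
#'   accuracies when available.
#' @export
glance.spin_metrics <- function(x, ...) {
  out <- tibble(
    n = x$n, n_excluded = x$n_excluded,
    acc_w = x$acc_w, f1_mw = x$f1_mw
  )
  if (!is.null(x$span)) {
    sp <- setNames(as.list(x$span$accuracy),
                   paste0("span_", x$span$boundary, "_acc"))
    out <- dplyr::bind_cols(out, as_tibble(sp))
  }
  out
}

#' Tidy a calibration report
#'
#' @param x A `spin_calibration` from [fit_temperature()].
#' @param ... Unused.
#' @return A tibble with the fitted temperature and the ECE before and
#'   after scaling.
#' @export
tidy.spin_calibration <- function(x, ...) {
  tibble(
    quantity = c("temperature", "ece_before", "ece_after"),
    value = c(x$temperature, x$ece_before, x$ece_after)
  )
}

#' @rdname tidy.spin_calibration
#' @export
glance.spin_calibration <- function(x, ...) {
  tibble(
    temperature = x$temperature, ece_before = x$ece_before,
    ece_after = x$ece_after, n = x$n, n_bins = x$n_bins
  )
}
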