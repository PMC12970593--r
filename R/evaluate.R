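#' One-vs-rest confusion counts per class
#'
#' Tallies, for every class `c` of the class set, the one-vs-rest true
#' positives, false positives, false negatives, and true negatives of a
#' set of predictions.
#'
#' @param truth True class labels.
#' @param estimate Predicted class labels, same length as `truth`.
#' @param classes Class set; defaults to the sorted union of both label
#'   vectors.
#' @return A tibble with columns `class`, `tp`, `fp`, `fn`, `tn`; rows
#'   sum to `length(truth)` for every class.
#' @export
confusion_counts <- function(truth, estimate, classes = NULL) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length.")
  }
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  classes <- as.character(classes %||% sort(unique(c(truth, estimate))))
  n <- length(truth)
  purrr::map_dfr(classes, function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn)
  })
}

.per_class_f1 <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  ifelse(denom == 0, 0, 2 * counts$tp / denom)
}

#' Macro-weighted F1 score
#'
#' Weighted mean of the per-class F1 scores,
#' `sum(W_c * F1_c) / sum(W_c)`, with
#' `F1_c = 2 TP_c / (2 TP_c + FP_c + FN_c)` and `F1_c` defined as 0 when
#' its denominator vanishes. With inverse-frequency weights this is the
#' primary model-selection metric.
#'
#' @param counts Confusion counts from [confusion_counts()].
#' @param weights Named class weights (see [compute_class_weights()]);
#'   must cover every class in `counts`.
#' @return Scalar in `[0, 1]`.
#' @export
macro_weighted_f1 <- function(counts, weights) {
  w <- .aligned_weights(counts, weights)
  sum(w * .per_class_f1(counts)) / sum(w)
}

#' Weighted accuracy
#'
#' Weighted mean of the per-class one-vs-rest accuracies
#' `(TP_c + TN_c) / (TP_c + TN_c + FP_c + FN_c)`. By default the sum is
#' normalized by `sum(W_c)`, which keeps the metric in `[0, 1]` under
#' class imbalance; `normalize = "classes"` divides by `|C|` instead
#' (the two agree when supports are balanced, since then every
#' `W_c = 1`).
#'
#' @inheritParams macro_weighted_f1
#' @param normalize Either `"weights"` (default, divide by `sum(W_c)`) or
#'   `"classes"` (divide by the class count).
#' @return Scalar; in `[0, 1]` under the default normalization.
#' @export
weighted_accuracy <- function(counts, weights,
                              normalize = c("weights", "classes")) {
  normalize <- match.arg(normalize)
  w <- .aligned_weights(counts, weights)
  acc <- (counts$tp + counts$tn) / (counts$tp + counts$tn + counts$fp + counts$fn)
  denom <- if (normalize == "weights") sum(w) else nrow(counts)
  sum(w * acc) / denom
}

.aligned_weights <- function(counts, weights) {
  if (sum(weights) <= 0) abort("Class weights must sum to a positive value.")
  missing <- setdiff(counts$class, names(weights))
  if (length(missing) > 0L) {
    abort(paste0("No weight supplied for class(es): ",
                 paste(missing, collapse = ", ")))
  }
  unname(weights[counts$class])
}

#' Domain-boundary accuracy within a tolerance
#'
#' Fraction of sequences whose predicted start (respectively end)
#' boundary lies within `tolerance` residues of the annotated boundary;
#' the two boundaries are scored independently. `tolerance = 0` is exact
#' match.
#'
#' @param pred_start,pred_end Predicted boundary positions.
#' @param true_start,true_end Annotated boundary positions, same length
#'   and coordinate convention as the predictions.
#' @param tolerance Non-negative integer tolerance in residues
#'   (default 3).
#' @return A tibble with one row per boundary: `boundary`
#'   (`"start"`/`"end"`) and `accuracy`.
#' @export
span_accuracy <- function(pred_start, true_start, pred_end, true_end,
                          tolerance = 3L) {
  if (tolerance < 0) abort("`tolerance` must be non-negative.")
  lens <- lengths(list(pred_start, true_start, pred_end, true_end))
  if (length(unique(lens)) != 1L) {
    abort("Boundary vectors must all have the same length.")
  }
  tibble(
    boundary = c("start", "end"),
    accuracy = c(
      mean(abs(pred_start - true_start) <= tolerance),
      mean(abs(pred_end - true_end) <= tolerance)
    )
  )
}

#' Bootstrap confidence intervals for span accuracy
#'
#' Resamples the paired predicted/annotated boundaries with replacement
#' `n_boot` times, recomputes [span_accuracy()] on each replicate, and
#' reports the replicate mean with a percentile confidence interval for
#' each boundary. Deterministic given `seed`.
#'
#' @inheritParams span_accuracy
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return A tibble with columns `boundary`, `mean`, `ci_low`, `ci_high`.
#' @export
bootstrap_span_ci <- function(pred_start, true_start, pred_end, true_end,
                              tolerance = 3L, n_boot = 1000L, level = 0.95,
                              seed = 1L) {
  n <- length(pred_start)
  if (n < 2L) abort("Need at least two boundary pairs to bootstrap.")
  if (n_boot < 1L) abort("`n_boot` must be at least 1.")
  hit_start <- abs(pred_start - true_start) <= tolerance
  hit_end <- abs(pred_end - true_end) <= tolerance
  reps <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    cbind(rowMeans(matrix(hit_start[idx], nrow = n_boot)),
          rowMeans(matrix(hit_end[idx], nrow = n_boot)))
  })
  alpha <- (1 - level) / 2
  purrr::map_dfr(1:2, function(k) {
    tibble(
      boundary = c("start", "end")[k],
      mean = mean(reps[, k]),
      ci_low = unname(quantile(reps[, k], alpha)),
      ci_high = unname(quantile(reps[, k], 1 - alpha))
    )
  })
}

#' Evaluate a fitted model on labeled data
#'
#' Runs the forward path on `data`, then computes the weighted accuracy,
#' macro-weighted F1, per-class F1, and (when the data carry span
#' annotations and the span predictor is active) boundary accuracies with
#' the given tolerance plus bootstrap confidence intervals. Class weights
#' are the inverse-frequency weights computed from the *training* supports
#' stored in the fit.
#'
#' @param fit A `spin_fit` object from [spin_train()].
#' @param data Tibble with `id`, `sequence`, `label`, and optionally
#'   `start`/`end` columns.
#' @param tolerance Residue tolerance for boundary accuracy (default 3).
#' @param n_boot Bootstrap replicates for the boundary CIs (default 1000;
#'   set to 0 to skip the bootstrap).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `spin_metrics`: a list with `acc_w`,
#'   `f1_mw`, `per_class` (tibble of per-class F1 and support), `span`
#'   (tibble or `NULL`), `counts`, `weights`, and `n`.
#' @export
spin_evaluate <- function(fit, data, tolerance = 3L, n_boot = 1000L,
                          seed = 1L) {
  stopifnot(inherits(fit, "spin_fit"))
  preds <- predict(fit, data)
  ok <- preds$status == "ok"
  truth <- as.character(data$label[ok])
  est <- preds$predicted_class[ok]
  counts <- confusion_counts(truth, est, classes = fit$classes)
  weights <- fit$class_weights
  per_class <- dplyr::mutate(
    counts,
    f1 = .per_class_f1(counts),
    support = counts$tp + counts$fn,
    weight = unname(weights[counts$class])
  )
  span_tbl <- NULL
  has_spans <- all(c("start", "end") %in% names(data)) &&
    !anyNA(data$start[ok]) && !anyNA(data$end[ok])
  if (has_spans && fit$config$use_span_predictor) {
    sa <- span_accuracy(preds$span_start[ok], data$start[ok],
                        preds$span_end[ok], data$end[ok],
                        tolerance = tolerance)
    if (n_boot > 0L) {
      ci <- bootstrap_span_ci(preds$span_start[ok], data$start[ok],
                              preds$span_end[ok], data$end[ok],
                              tolerance = tolerance, n_boot = n_boot,
                              seed = seed)
      span_tbl <- dplyr::left_join(sa, ci, by = "boundary")
    } else {
      span_tbl <- sa
    }
    span_tbl$tolerance <- tolerance
  }
  structure(
    list(
      acc_w = weighted_accuracy(counts, weights),
      f1_mw = macro_weighted_f1(counts, weights),
      per_class = dplyr::select(per_class, "class", "support", "weight",
                                "f1", "tp", "fp", "fn", "tn"),
      span = span_tbl, counts = counts, weights = weights,
      n = sum(ok), n_excluded = sum(!ok)
    ),
    class = "spin_metrics"
  )
}

#' @export
print.spin_metrics <- function(x, ...) {
  cat(sprintf("<spin_metrics> n = %d (excluded %d)\n", x$n, x$n_excluded))
  cat(sprintf("  weighted accuracy  %.4f\n", x$acc_w))
  cat(sprintf("  macro-weighted F1  %.4f\n", x$f1_mw))
  if (!is.null(x$span)) {
    for (i in seq_len(nrow(x$span))) {
      cat(sprintf("  span %-5s acc (+/-%d)  %.4f", x$span$boundary[i],
                  x$span$tolerance[i], x$span$accuracy[i]))
      if ("ci_low" %in% names(x$span)) {
        cat(sprintf("  [%.4f, %.4f]", x$span$ci_low[i], x$span$ci_high[i]))
      }
      cat("\n")
    }
  }
  invisible(x)
}
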