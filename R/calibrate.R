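#' Fit a temperature-scaling calibration model
#'
#' Finds the scalar temperature `T` minimizing the negative log-likelihood
#' of `softmax(logits / T)` against the labels, by bounded 1-D search on
#' `[0.05, 20]` with tolerance `1e-4`. Dividing logits by a positive
#' scalar is monotone per sample, so the predicted class of every sample
#' is unchanged; this is asserted before returning. Expected calibration
#' error before and after scaling is recorded on the fitting set.
#'
#' @param logits Numeric `n x C` matrix of pre-softmax classifier scores.
#' @param labels True labels; either 1-based column indices or values of
#'   `classes`.
#' @param classes Optional class labels naming the columns of `logits`.
#' @param n_bins Bin count for the ECE bookkeeping (default 10).
#' @param interval Search bracket for `T`.
#' @param tol Search tolerance.
#' @return An object of class `spin_calibration` with `temperature`,
#'   `ece_before`, `ece_after`, `n_bins`, and `nll` at the optimum.
#' @export
fit_temperature <- function(logits, labels, classes = NULL, n_bins = 10L,
                            interval = c(0.05, 20), tol = 1e-4) {
  logits <- rbind(logits)
  idx <- .label_index(labels, classes, ncol(logits))
  if (length(unique(idx)) < 2L) {
    abort("Temperature fitting needs at least two represented classes.",
          class = "spinr_calibration_error")
  }
  nll <- function(temp) {
    scaled <- logits / temp
    m <- apply(scaled, 1L, max)
    lse <- m + log(rowSums(exp(scaled - m)))
    mean(lse - scaled[cbind(seq_along(idx), idx)])
  }
  opt <- optimize(nll, interval = interval, tol = tol)
  if (!is.finite(opt$objective)) {
    abort("Temperature search did not converge to a finite objective.",
          class = "spinr_calibration_error")
  }
  temp <- opt$minimum
  before <- .probs_from_logits(logits, 1)
  after <- .probs_from_logits(logits, temp)
  if (!all(max.col(before, ties.method = "first") ==
             max.col(after, ties.method = "first"))) {
    abort("Temperature scaling changed a predicted class; this should be impossible.",
          class = "spinr_calibration_error")
  }
  structure(
    list(
      temperature = temp,
      ece_before = expected_calibration_error(before, idx, n_bins = n_bins),
      ece_after = expected_calibration_error(after, idx, n_bins = n_bins),
      n_bins = as.integer(n_bins), nll = opt$objective, n = nrow(logits)
    ),
    class = "spin_calibration"
  )
}

.probs_from_logits <- function(logits, temp) {
  scaled <- logits / temp
  e <- exp(scaled - apply(scaled, 1L, max))
  e / rowSums(e)
}

.label_index <- function(labels, classes, n_col) {
  if (is.numeric(labels) && is.null(classes)) {
    idx <- as.integer(labels)
  } else {
    classes <- as.character(classes %||% sort(unique(as.character(labels))))
    idx <- match(as.character(labels), classes)
  }
  if (anyNA(idx) || any(idx < 1L) || any(idx > n_col)) {
    abort("Labels do not map onto the logit/probability columns.")
  }
  idx
}

#' Expected calibration error
#'
#' Partitions samples by top-class confidence into `n_bins` equal-width
#' bins over `(0, 1]` and returns the bin-size-weighted mean absolute gap
#' between within-bin accuracy and within-bin mean confidence. Empty bins
#' contribute nothing.
#'
#' @param probs Numeric `n x C` matrix of class probabilities.
#' @param labels True labels (1-based indices or values of `classes`).
#' @param classes Optional class labels for the columns of `probs`.
#' @param n_bins Number of equal-width confidence bins (default 10).
#' @return Scalar ECE in `[0, 1]`.
#' @export
expected_calibration_error <- function(probs, labels, classes = NULL,
                                       n_bins = 10L) {
  probs <- rbind(probs)
  idx <- .label_index(labels, classes, ncol(probs))
  conf <- apply(probs, 1L, max)
  pred <- max.col(rbind(probs), ties.method = "first")
  correct <- pred == idx
  bin <- pmax(pmin(ceiling(conf * n_bins), n_bins), 1L)
  n <- length(conf)
  ece <- 0
  for (b in unique(bin)) {
    in_bin <- bin == b
    ece <- ece + sum(in_bin) / n * abs(mean(correct[in_bin]) - mean(conf[in_bin]))
  }
  ece
}

#' Classify with confidence-threshold abstention
#'
#' Assigns the argmax class when the top-class confidence reaches the
#' threshold and the reserved label `"UNKNOWN"` otherwise. A threshold of
#' 0 never abstains; the abstention fraction is monotone non-decreasing
#' in the threshold.
#'
#' @param probs Numeric `n x C` matrix of (calibrated) class
#'   probabilities, or a prediction tibble from [predict.spin_fit()]
#'   (columns `predicted_class` and `probability`).
#' @param threshold Confidence threshold in `[0, 1]`.
#' @param classes Optional class labels for matrix input.
#' @return A tibble with columns `label` (class or `"UNKNOWN"`),
#'   `confidence`, and `threshold`.
#' @export
classify_with_abstention <- function(probs, threshold, classes = NULL) {
  if (threshold < 0 || threshold > 1) abort("`threshold` must lie in [0, 1].")
  if (is.data.frame(probs)) {
    conf <- probs$probability
    pred <- probs$predicted_class
  } else {
    probs <- rbind(probs)
    classes <- as.character(classes %||% seq_len(ncol(probs)))
    conf <- apply(probs, 1L, max)
    pred <- classes[max.col(probs, ties.method = "first")]
  }
  tibble(
    label = ifelse(conf < threshold, "UNKNOWN", pred),
    confidence = conf,
    threshold = threshold
  )
}

#' Compare in-family and out-of-family confidence distributions
#'
#' Bins the top-class confidences of two prediction sets on a common
#' grid over `[0, 1]` and locates the lowest crossing point of the two
#' binned densities, which serves as a suggested abstention threshold
#' separating in-family (right-skewed) from out-of-family (left-skewed)
#' confidence profiles.
#'
#' @param conf_in,conf_out Numeric vectors of top-class confidences for
#'   the in-family and out-of-family sets.
#' @param n_bins Number of equal-width bins over `[0, 1]` (default 20).
#' @return A list of class `spin_confidence_split`: `histogram` (tibble
#'   with `bin_mid`, `density_in`, `density_out`), `threshold`
#'   (suggested crossing point, `NA` if none), and the input summaries.
#'   Warns when the two distributions are indistinguishable.
#' @export
confidence_distributions <- function(conf_in, conf_out, n_bins = 20L) {
  if (length(conf_in) == 0L || length(conf_out) == 0L) {
    abort("Both confidence sets must be non-empty.")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h_in <- graphics::hist(pmin(pmax(conf_in, 0), 1), breaks = breaks, plot = FALSE)
  h_out <- graphics::hist(pmin(pmax(conf_out, 0), 1), breaks = breaks, plot = FALSE)
  diff_d <- h_in$density - h_out$density
  if (all(diff_d == 0)) {
    warn("In-family and out-of-family confidence distributions are identical; no separating threshold exists.",
         class = "spinr_no_separation")
    threshold <- NA_real_
  } else {
    threshold <- NA_real_
    sgn <- sign(diff_d)
    nz <- which(sgn != 0)
    # lowest boundary where the density difference changes sign (zero-density
    # gaps between the two supports are skipped over)
    for (k in seq_along(nz)[-1L]) {
      if (sgn[nz[k]] != sgn[nz[k - 1L]]) {
        threshold <- (h_in$mids[nz[k - 1L]] + h_in$mids[nz[k]]) / 2
        break
      }
    }
    if (is.na(threshold)) {
      warn("Binned densities never cross; the two sets are not separable by a single threshold.",
           class = "spinr_no_separation")
    }
  }
  structure(
    list(
      histogram = tibble(
        bin_mid = h_in$mids,
        density_in = h_in$density,
        density_out = h_out$density
      ),
      threshold = threshold,
      mean_in = mean(conf_in), mean_out = mean(conf_out),
      n_in = length(conf_in), n_out = length(conf_out)
    ),
    class = "spin_confidence_split"
  )
}

#' Calibrate a fitted model on validation data
#'
#' Computes classifier logits for the validation set, fits the
#' temperature by [fit_temperature()], and returns the fit with the
#' temperature attached so that subsequent [predict.spin_fit()] calls
#' report calibrated confidences. The calibration report is stored in
#' `fit$calibration`.
#'
#' @param fit A `spin_fit` object.
#' @param validation Labeled tibble (`id`, `sequence`, `label`).
#' @param n_bins ECE bin count (default 10).
#' @return The fit with `temperature` set and `calibration` attached.
#' @export
spin_calibrate <- function(fit, validation, n_bins = 10L) {
  stopifnot(inherits(fit, "spin_fit"))
  lg <- .fit_logits(fit, validation)
  cal <- fit_temperature(lg$logits, lg$labels, classes = fit$classes,
                         n_bins = n_bins)
  fit$temperature <- cal$temperature
  fit$calibration <- cal
  fit
}

# Classifier logits for every valid record of `data` under a fit.
.fit_logits <- function(fit, data) {
  emb <- .embed_records(data, fit$encoder, fit$config)
  keep <- !purrr::map_lgl(emb, is.null)
  logits <- t(vapply(
    emb[keep],
    function(E) {
      out <- .forward_one(E, fit$params, fit$config$use_span_predictor)
      classifier_logits(out$pooled, fit$params$head)
    },
    numeric(fit$config$n_classes)
  ))
  list(logits = logits, labels = as.character(data$label)[keep])
}

#' @export
print.spin_calibration <- function(x, ...) {
  cat(sprintf(
    "<spin_calibration> T = %.4f (n = %d, %d bins)\n  ECE before %.4f -> after %.4f\n",
    x$temperature, x$n, x$n_bins, x$ece_before, x$ece_after
  ))
  invisible(x)
}
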