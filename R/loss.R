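#' Inverse-frequency class weights
#'
#' Computes `W_c = N / (|C| * s_c)` where `s_c` is the support of class
#' `c` among `labels` and `N` the total sample count. Balanced supports
#' give every class weight 1; rare classes receive proportionally larger
#' weights. These weights enter both the classification loss and the
#' imbalance-aware metrics.
#'
#' @param labels Vector of class labels (character or factor).
#' @param classes Optional full class set; every class must be present in
#'   `labels`.
#' @return Named numeric vector of positive weights, one per class.
#' @export
#' @examples
#' compute_class_weights(rep(c("a", "b"), c(90, 10)))  # 5/9 and 5
compute_class_weights <- function(labels, classes = NULL) {
  labels <- as.character(labels)
  classes <- as.character(classes %||% sort(unique(labels)))
  support <- table(factor(labels, levels = classes))
  empty <- classes[support == 0L]
  if (length(empty) > 0L) {
    abort(
      paste0("Class weight undefined for empty class(es): ",
             paste(empty, collapse = ", ")),
      class = "spinr_empty_class"
    )
  }
  n <- length(labels)
  setNames(n / (length(classes) * as.numeric(support)), classes)
}

#' Weighted classification cross-entropy
#'
#' Mean over the batch of `-log p(true class) * W(true class)`, with the
#' probability of the true class clamped at `1e-12` so confident mistakes
#' stay finite.
#'
#' @param probs Numeric matrix (`n x C`) of class probabilities, columns
#'   in the order of `classes`.
#' @param labels True labels (values of `classes`).
#' @param weights Named class weights, as from [compute_class_weights()].
#' @param classes Class set defining the column order; defaults to
#'   `names(weights)`.
#' @return Non-negative scalar loss.
#' @export
classification_loss <- function(probs, labels, weights,
                                classes = names(weights)) {
  probs <- rbind(probs)
  labels <- as.character(labels)
  idx <- match(labels, classes)
  if (anyNA(idx)) {
    abort(paste0("Label(s) outside the class set: ",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")),
          class = "spinr_label_error")
  }
  if (nrow(probs) != length(labels)) abort("`probs` and `labels` lengths differ.")
  p_true <- pmax(probs[cbind(seq_along(idx), idx)], 1e-12)
  mean(-log(p_true) * unname(weights[labels]))
}

#' Span cross-entropy loss
#'
#' The mean over the batch of the average of the start-position and
#' end-position cross-entropies, each taken over the softmax of the
#' corresponding logit column across residue positions.
#'
#' @param span_logits List of `L x 2` logit matrices, one per sample.
#' @param starts,ends True 0-based start/end token indices.
#' @return Non-negative scalar loss.
#' @export
span_loss <- function(span_logits, starts, ends) {
  if (length(span_logits) != length(starts) || length(starts) != length(ends)) {
    abort("`span_logits`, `starts` and `ends` must have equal length.")
  }
  if (anyNA(starts) || anyNA(ends)) {
    abort("Missing span annotation in a span-mode batch.",
          class = "spinr_annotation_error")
  }
  per_sample <- purrr::pmap_dbl(
    list(span_logits, starts, ends),
    function(lg, s, e) {
      L <- nrow(lg)
      if (s < 0L || e < 0L || s >= L || e >= L) {
        abort("True span index outside the logit range.")
      }
      ce_s <- -.log_softmax(lg[, 1L])[s + 1L]
      ce_e <- -.log_softmax(lg[, 2L])[e + 1L]
      (ce_s + ce_e) / 2
    }
  )
  mean(per_sample)
}

#' Combine the classification and span losses
#'
#' `total = w_class * l_class + w_span * l_span` when a span term is
#' present (default weights 0.7 / 0.3); with unannotated spans the total
#' is the classification term alone.
#'
#' @param l_class Non-negative classification loss.
#' @param l_span Non-negative span loss, or `NULL` when spans are not
#'   annotated.
#' @param w_class,w_span Loss weights.
#' @return A list of class `spin_loss` with `l_class`, `l_span` (may be
#'   `NA`), and `total`.
#' @export
total_loss <- function(l_class, l_span = NULL, w_class = 0.7, w_span = 0.3) {
  if (l_class < 0 || (!is.null(l_span) && l_span < 0)) {
    abort("Loss components must be non-negative.", class = "spinr_numeric_error")
  }
  total <- if (is.null(l_span)) l_class else w_class * l_class + w_span * l_span
  structure(
    list(l_class = l_class, l_span = l_span %||% NA_real_, total = total),
    class = "spin_loss"
  )
}
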