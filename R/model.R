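#' Model configuration
#'
#' Bundles the architectural settings that are stored with every
#' checkpoint: class count, the 1024-token length cap, hidden sizes, the
#' dropout rate used during training, the multi-task loss weights (0.7 on
#' classification, 0.3 on span prediction), and whether the domain span
#' predictor is active.
#'
#' @param n_classes Number of functional classes (>= 2).
#' @param max_length Maximum token count including the classification
#'   token; longer sequences are excluded.
#' @param hidden_dim Width `d` of the encoder embeddings.
#' @param classifier_hidden Width of the classifier's hidden layer.
#' @param n_frozen_layers Encoder layers kept frozen during fine-tuning.
#' @param dropout Dropout rate applied in the classifier head at training
#'   time only.
#' @param w_class,w_span Loss weights; must be positive and sum to 1.
#' @param use_span_predictor If `FALSE` the span module is skipped and the
#'   whole residue range is pooled.
#' @return A list of class `spin_config`.
#' @export
spin_config <- function(n_classes, max_length = 1024L, hidden_dim = 64L,
                        classifier_hidden = 64L, n_frozen_layers = 6L,
                        dropout = 0.1, w_class = 0.7, w_span = 0.3,
                        use_span_predictor = TRUE) {
  if (n_classes < 2L) abort("`n_classes` must be at least 2.")
  if (!(w_class > 0 && w_class < 1) || abs(w_class + w_span - 1) > 1e-12) {
    abort("Loss weights must satisfy 0 < w_class < 1 and w_class + w_span = 1.")
  }
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  structure(
    list(
      n_classes = as.integer(n_classes), max_length = as.integer(max_length),
      hidden_dim = as.integer(hidden_dim),
      classifier_hidden = as.integer(classifier_hidden),
      n_frozen_layers = as.integer(n_frozen_layers), dropout = dropout,
      w_class = w_class, w_span = w_span,
      use_span_predictor = isTRUE(use_span_predictor)
    ),
    class = "spin_config"
  )
}

.softmax <- function(x) {
  finite <- is.finite(x)
  if (!any(finite)) abort("All logits are masked.", class = "spinr_degenerate_logits")
  z <- x - max(x[finite])
  e <- ifelse(is.finite(z), exp(z), 0)
  e / sum(e)
}

.log_softmax <- function(x) {
  finite <- is.finite(x)
  z <- x - max(x[finite])
  z - log(sum(exp(z[finite])))
}

#' Select a domain span from start/end position logits
#'
#' Takes the `L x 2` per-residue logits of the span predictor (column 1 =
#' start scores, column 2 = end scores; masked positions carry `-Inf`) and
#' returns the argmax start and end token indices, 0-based over residues.
#' Ties break to the lowest index. If the selected end does not come
#' strictly after the selected start, the prediction falls back to the
#' whole residue range and the `fallback` flag is set; no further length
#' or ordering check is performed.
#'
#' @param logits Numeric `L x 2` matrix of span scores.
#' @return A list of class `spin_span` with `t_start`, `t_end` (0-based
#'   residue indices), `start_conf`, `end_conf` (softmax probabilities of
#'   the selected positions), and `fallback`.
#' @export
predict_span <- function(logits) {
  if (!is.matrix(logits) || ncol(logits) != 2L || nrow(logits) < 1L) {
    abort("`logits` must be an L x 2 matrix.")
  }
  L <- nrow(logits)
  p_start <- .softmax(logits[, 1L])
  p_end <- .softmax(logits[, 2L])
  t_start <- which.max(replace(logits[, 1L], !is.finite(logits[, 1L]), -Inf)) - 1L
  t_end <- which.max(replace(logits[, 2L], !is.finite(logits[, 2L]), -Inf)) - 1L
  start_conf <- p_start[t_start + 1L]
  end_conf <- p_end[t_end + 1L]
  if (t_end <= t_start) {
    return(structure(
      list(t_start = 0L, t_end = L - 1L, start_conf = start_conf,
           end_conf = end_conf, fallback = TRUE),
      class = "spin_span"
    ))
  }
  structure(
    list(t_start = t_start, t_end = t_end, start_conf = start_conf,
         end_conf = end_conf, fallback = FALSE),
    class = "spin_span"
  )
}

#' Mean-pool embeddings over a predicted span
#'
#' Averages the residue rows of an embedding matrix over the inclusive
#' span `[t_start, t_end]`. The classification-token row (row 1) is
#' removed before indexing and never contributes. When the span carries
#' the fallback flag, or the span predictor is disabled, the mean is taken
#' over all residue rows.
#'
#' @param emb `N x d` embedding matrix, classification token in row 1.
#' @param span A [predict_span()] result (or `NULL` to pool everything).
#' @param use_span_predictor Set `FALSE` to force whole-sequence pooling.
#' @return Numeric vector of length `d`.
#' @export
pool_span <- function(emb, span = NULL, use_span_predictor = TRUE) {
  if (!is.matrix(emb) || nrow(emb) < 2L) {
    abort("`emb` must have a classification-token row plus residue rows.")
  }
  residues <- emb[-1L, , drop = FALSE]
  if (is.null(span) || !use_span_predictor || isTRUE(span$fallback)) {
    return(colMeans(residues))
  }
  if (span$t_start < 0L || span$t_end >= nrow(residues)) {
    abort("Span indices fall outside the residue rows of `emb`.")
  }
  colMeans(residues[(span$t_start + 1L):(span$t_end + 1L), , drop = FALSE])
}

#' Classifier head: pooled vector to class probabilities
#'
#' Applies the Dense -> Tanh -> Dense head (dropout disabled, as at
#' inference) and a softmax, returning normalized class probabilities.
#' The argmax class breaks ties to the lowest index.
#'
#' @param pooled Numeric vector of length `d`.
#' @param head List with `W1` (`d x h`), `b1`, `W2` (`h x C`), `b2`.
#' @return List of class `spin_probs` with `probs` (length `C`, sums to
#'   1) and `predicted_class` (1-based index of the maximum).
#' @export
classify <- function(pooled, head) {
  logits <- classifier_logits(pooled, head)
  if (any(!is.finite(logits))) {
    abort("Non-finite classifier logits.", class = "spinr_numeric_error")
  }
  probs <- .softmax(logits)
  structure(
    list(probs = probs, predicted_class = which.max(probs)),
    class = "spin_probs"
  )
}

#' Raw classifier logits (pre-softmax)
#'
#' Exposed separately because temperature scaling operates on logits.
#'
#' @inheritParams classify
#' @return Numeric vector of length `C`.
#' @export
classifier_logits <- function(pooled, head) {
  if (length(pooled) != nrow(head$W1)) {
    abort(sprintf(
      "Pooled vector has length %d but the head expects %d.",
      length(pooled), nrow(head$W1)
    ))
  }
  hidden <- tanh(drop(crossprod(head$W1, pooled)) + head$b1)
  drop(crossprod(head$W2, hidden)) + head$b2
}

# Span logits for one sequence: linear layer applied to each residue row.
.span_logits <- function(res_emb, params) {
  res_emb %*% params$W_span +
    matrix(params$b_span, nrow(res_emb), 2L, byrow = TRUE)
}

# Full forward pass for one precomputed residue-embedding matrix.
.forward_one <- function(res_emb, params, use_span) {
  if (use_span) {
    span <- predict_span(.span_logits(res_emb, params))
    pooled <- if (span$fallback) colMeans(res_emb) else
      colMeans(res_emb[(span$t_start + 1L):(span$t_end + 1L), , drop = FALSE])
  } else {
    span <- structure(
      list(t_start = 0L, t_end = nrow(res_emb) - 1L, start_conf = NA_real_,
           end_conf = NA_real_, fallback = TRUE),
      class = "spin_span"
    )
    pooled <- colMeans(res_emb)
  }
  cls <- classify(pooled, params$head)
  list(span = span, probs = cls$probs, predicted_class = cls$predicted_class,
       pooled = pooled)
}

#' Run the full forward path over a table of sequences
#'
#' Tokenizes, encodes, predicts a span (unless disabled), pools, and
#' classifies every row of `data`. Records that fail tokenization (empty
#' or over-length sequences) are reported in the `status` column with `NA`
#' outputs instead of aborting the batch. Because every sequence is
#' processed at its own length, batched and one-by-one calls are
#' identical by construction.
#'
#' @param data Tibble with at least `id` and `sequence` columns.
#' @param encoder A [new_spin_encoder()] object.
#' @param config A [spin_config()].
#' @param params Model parameters (span head + classifier head), e.g.
#'   from a fitted model's `$params`.
#' @param temperature Optional temperature divisor applied to classifier
#'   logits before the softmax (confidence calibration).
#' @param classes Optional class labels used to name probability columns.
#' @return A tibble with one row per input row: `id`, `status`
#'   (`"ok"`/`"excluded"`/`"invalid"`), 1-based `span_start`/`span_end`,
#'   `span_fallback`, `predicted_class`, `probability` (top-class
#'   confidence), and one `prob_*` column per class.
#' @export
spin_forward <- function(data, encoder, config, params, temperature = NULL,
                         classes = NULL) {
  stopifnot(inherits(encoder, "spin_encoder"), inherits(config, "spin_config"))
  classes <- classes %||% as.character(seq_len(config$n_classes))
  temp <- temperature %||% 1
  rows <- purrr::pmap(
    list(data$id, data$sequence),
    function(id, sequence) {
      tok <- tryCatch(
        tokenize(sequence, max_length = config$max_length, id = id),
        spinr_excluded_record = function(e) e,
        spinr_invalid_record = function(e) e
      )
      if (inherits(tok, "condition")) {
        status <- if (inherits(tok, "spinr_excluded_record")) "excluded" else "invalid"
        return(c(list(id = id, status = status, span_start = NA_integer_,
                      span_end = NA_integer_, span_fallback = NA,
                      predicted_class = NA_character_, probability = NA_real_),
                 setNames(rep(NA_real_, length(classes)),
                          paste0("prob_", classes))))
      }
      emb <- encoder$encode(tok$ids)
      res_emb <- emb[-1L, , drop = FALSE]
      out <- .forward_one(res_emb, params, config$use_span_predictor)
      logits <- classifier_logits(out$pooled, params$head)
      probs <- .softmax(logits / temp)
      c(list(id = id, status = "ok",
             span_start = out$span$t_start + 1L,
             span_end = out$span$t_end + 1L,
             span_fallback = out$span$fallback,
             predicted_class = classes[which.max(probs)],
             probability = max(probs)),
        setNames(as.list(probs), paste0("prob_", classes)))
    }
  )
  dplyr::bind_rows(rows)
}
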