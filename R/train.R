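#' Training hyperparameter configuration
#'
#' Defaults follow the tuned recipe: AdamW (decoupled weight decay 0.01)
#' at learning rate `1e-4`, a cosine-annealed schedule whose warmup
#' covers 10% of the total steps, 10 epochs, training batches of 8 and
#' evaluation batches of 32, and a three-seed repetition protocol.
#'
#' @param learning_rate Peak learning rate.
#' @param weight_decay Decoupled weight-decay coefficient (applied to
#'   weight matrices, not biases).
#' @param epochs Training epochs.
#' @param batch_size,eval_batch_size Batch sizes for training and
#'   evaluation.
#' @param warmup_frac Fraction of total steps spent in linear warmup.
#' @param beta1,beta2,eps Adam moment coefficients.
#' @param seeds Seeds used by [spin_train_seeds()].
#' @return A list of class `spin_train_config`.
#' @export
spin_train_config <- function(learning_rate = 1e-4, weight_decay = 0.01,
                              epochs = 10L, batch_size = 8L,
                              eval_batch_size = 32L, warmup_frac = 0.10,
                              beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                              seeds = c(1L, 2L, 3L)) {
  if (learning_rate <= 0 || weight_decay < 0 || epochs < 1L || batch_size < 1L) {
    abort("Rates must be positive and counts at least 1.")
  }
  structure(
    list(
      learning_rate = learning_rate, weight_decay = weight_decay,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      eval_batch_size = as.integer(eval_batch_size),
      warmup_frac = warmup_frac, beta1 = beta1, beta2 = beta2, eps = eps,
      seeds = as.integer(seeds)
    ),
    class = "spin_train_config"
  )
}

#' Split records into train / validation / test partitions
#'
#' Shuffles the rows (deterministically under `seed`) and cuts them into
#' disjoint, exhaustive partitions whose sizes are the cumulative-floor
#' rounding of `fractions * n` — e.g. 28,151 records at (0.8, 0.1, 0.1)
#' give 22,520 / 2,815 / 2,816. Stratified mode (the default when labels
#' are present) applies the same rule within every class so that class
#' proportions are preserved within rounding.
#'
#' @param data Tibble of records; needs a `label` column when
#'   `stratified = TRUE`.
#' @param fractions Three fractions summing to 1 (train, validation,
#'   test).
#' @param seed Integer seed controlling the shuffle.
#' @param stratified Preserve class proportions across the partitions.
#' @return A named list of tibbles: `train`, `validation`, `test`.
#' @export
split_dataset <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          stratified = TRUE) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three values summing to 1.")
  }
  if (stratified) {
    if (!"label" %in% names(data)) {
      abort("Stratified splitting needs a `label` column.")
    }
    sizes <- table(data$label)
    small <- names(sizes)[sizes < 3L]
    if (length(small) > 0L) {
      abort(
        paste0("Class(es) too small to stratify (need >= 3 members): ",
               paste(small, collapse = ", ")),
        class = "spinr_stratification_error"
      )
    }
  }
  assign_one <- function(idx, shuffled) {
    cuts <- c(0L, floor(cumsum(fractions)[1:2] * length(idx)), length(idx))
    part <- rep(c("train", "validation", "test"), diff(cuts))
    split(shuffled, factor(part, levels = c("train", "validation", "test")))
  }
  parts <- withr::with_seed(seed, {
    if (stratified) {
      by_class <- split(seq_len(nrow(data)), data$label)
      pieces <- lapply(by_class, function(idx) assign_one(idx, sample(idx)))
      list(
        train = unlist(lapply(pieces, `[[`, "train"), use.names = FALSE),
        validation = unlist(lapply(pieces, `[[`, "validation"), use.names = FALSE),
        test = unlist(lapply(pieces, `[[`, "test"), use.names = FALSE)
      )
    } else {
      idx <- seq_len(nrow(data))
      assign_one(idx, sample(idx))
    }
  })
  lapply(parts, function(idx) data[sort(idx), , drop = FALSE])
}

# Residue-embedding matrices (classification-token row removed) for every
# record; NULL where tokenization rejects the record. `strict` aborts on
# the first rejected record instead.
.embed_records <- function(data, encoder, config, strict = FALSE) {
  purrr::map2(data$id, data$sequence, function(id, sq) {
    tok <- tryCatch(
      tokenize(sq, max_length = config$max_length, id = id),
      spinr_excluded_record = function(e) if (strict) stop(e) else NULL,
      spinr_invalid_record = function(e) if (strict) stop(e) else NULL
    )
    if (is.null(tok)) return(NULL)
    encoder$encode(tok$ids)[-1L, , drop = FALSE]
  })
}

.init_params <- function(d, config) {
  gauss <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  h <- config$classifier_hidden
  list(
    W_span = gauss(d, 2L), b_span = numeric(2L),
    head = list(
      W1 = gauss(d, h), b1 = numeric(h),
      W2 = gauss(h, config$n_classes), b2 = numeric(config$n_classes)
    )
  )
}

.zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

.cosine_lr <- function(step, total, warmup, peak) {
  if (warmup > 0 && step <= warmup) return(peak * step / warmup)
  progress <- (step - warmup) / max(total - warmup, 1)
  peak * 0.5 * (1 + cos(pi * progress))
}

# One AdamW update, in place over the nested parameter list. Decoupled
# weight decay is applied to matrices only.
.adamw_step <- function(params, grads, state, lr, tc) {
  walk_names <- function(p, g, m, v, path) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        res <- walk_names(p[[nm]], g[[nm]], m[[nm]], v[[nm]], c(path, nm))
        out_p[[nm]] <- res$p; out_m[[nm]] <- res$m; out_v[[nm]] <- res$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- tc$beta1 * m + (1 - tc$beta1) * g
    v2 <- tc$beta2 * v + (1 - tc$beta2) * g^2
    mh <- m2 / (1 - tc$beta1^state$t)
    vh <- v2 / (1 - tc$beta2^state$t)
    p2 <- p - lr * mh / (sqrt(vh) + tc$eps)
    if (is.matrix(p)) p2 <- p2 - lr * tc$weight_decay * p
    list(p = p2, m = m2, v = v2)
  }
  res <- walk_names(params, grads, state$m, state$v, character())
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# Forward + backward for one sample; returns gradient contributions and
# loss components. Class gradients are scaled by w_class and the sample's
# class weight; span gradients by w_span. Dropout masks are drawn from
# the session RNG (inverted dropout).
.sample_grads <- function(E, label_idx, s0, e0, params, config, w_sample,
                          use_span, dropout) {
  d <- ncol(E)
  g <- list()
  out <- list()
  # span branch
  if (use_span) {
    lg <- .span_logits(E, params)
    span <- predict_span(lg)
    ls_s <- .log_softmax(lg[, 1L]); ls_e <- .log_softmax(lg[, 2L])
    l_span <- NA_real_
    if (!is.na(s0)) {
      q_s <- exp(ls_s); q_e <- exp(ls_e)
      l_span <- -(ls_s[s0 + 1L] + ls_e[e0 + 1L]) / 2
      d_s <- q_s / 2; d_s[s0 + 1L] <- d_s[s0 + 1L] - 0.5
      d_e <- q_e / 2; d_e[e0 + 1L] <- d_e[e0 + 1L] - 0.5
      g$W_span <- crossprod(E, cbind(d_s, d_e))
      g$b_span <- c(sum(d_s), sum(d_e))
    }
    pooled <- if (span$fallback) colMeans(E) else
      colMeans(E[(span$t_start + 1L):(span$t_end + 1L), , drop = FALSE])
    out$span <- span
    out$l_span <- l_span
  } else {
    pooled <- colMeans(E)
    out$l_span <- NA_real_
  }
  # classifier branch with inverted dropout
  keep <- 1 - dropout
  m1 <- if (dropout > 0) stats::rbinom(d, 1L, keep) / keep else rep(1, d)
  z <- pooled * m1
  a <- drop(crossprod(params$head$W1, z)) + params$head$b1
  tv <- tanh(a)
  h <- length(tv)
  m2 <- if (dropout > 0) stats::rbinom(h, 1L, keep) / keep else rep(1, h)
  t2 <- tv * m2
  logits <- drop(crossprod(params$head$W2, t2)) + params$head$b2
  p <- .softmax(logits)
  l_class <- w_sample * -log(max(p[label_idx], 1e-12))
  g_o <- w_sample * p
  g_o[label_idx] <- g_o[label_idx] - w_sample
  g$head <- list(
    W2 = tcrossprod(t2, g_o),
    b2 = g_o,
    W1 = NULL, b1 = NULL
  )
  g_t <- drop(params$head$W2 %*% g_o) * m2
  g_a <- g_t * (1 - tv^2)
  g$head$W1 <- tcrossprod(z, g_a)
  g$head$b1 <- g_a
  out$l_class <- l_class
  out$grads <- g
  out
}

.accumulate <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]] <- if (is.list(g[[nm]])) .accumulate(acc[[nm]], g[[nm]]) else
      (if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]])
  }
  acc
}

.scale_grads <- function(g, f) rapply(g, function(x) x * f, how = "replace")

#' Train the span predictor and classifier heads
#'
#' Fits the model on embedded training records with the weighted
#' multi-task objective `0.7 * L_class + 0.3 * L_span` (the span term is
#' dropped when annotations are absent), AdamW, and a cosine schedule
#' with 10% warmup. The classification loss carries inverse-frequency
#' class weights computed from the training supports. After every epoch
#' the macro-weighted F1 is evaluated on the validation set and the
#' parameters of the best epoch are kept (ties resolve to the earliest
#' epoch). The encoder itself is frozen — only the heads carry gradients
#' — mirroring a frozen-backbone fine-tuning regime. Fully reproducible
#' given `seed`.
#'
#' @param train,validation Labeled record tibbles (`id`, `sequence`,
#'   `label`, optional `start`/`end` span columns, 1-based inclusive).
#' @param encoder A [new_spin_encoder()]; its embedding width must match
#'   nothing in advance — the heads are sized from it.
#' @param config A [spin_config()]. If span annotations are absent from
#'   `train`, the span predictor is skipped regardless of
#'   `use_span_predictor`.
#' @param train_config A [spin_train_config()].
#' @param seed Integer seed covering initialization, shuffling, and
#'   dropout.
#' @return An object of class `spin_fit`: parameters of the best epoch,
#'   configs, class labels and weights, the per-epoch training log, and
#'   bookkeeping for checkpoints.
#' @export
spin_train <- function(train, validation, encoder, config,
                       train_config = spin_train_config(), seed = 1L) {
  stopifnot(inherits(encoder, "spin_encoder"), inherits(config, "spin_config"))
  classes <- sort(unique(as.character(train$label)))
  if (length(classes) != config$n_classes) {
    abort(sprintf("Training data contain %d classes but `config$n_classes` is %d.",
                  length(classes), config$n_classes))
  }
  has_spans <- all(c("start", "end") %in% names(train)) &&
    !anyNA(train$start) && !anyNA(train$end)
  use_span <- config$use_span_predictor && has_spans
  config$use_span_predictor <- use_span
  weights <- compute_class_weights(train$label, classes)

  emb_train <- .embed_records(train, encoder, config, strict = TRUE)
  label_idx <- match(as.character(train$label), classes)
  w_sample <- unname(weights[as.character(train$label)])
  s0 <- if (has_spans) as.integer(train$start) - 1L else rep(NA_integer_, nrow(train))
  e0 <- if (has_spans) as.integer(train$end) - 1L else rep(NA_integer_, nrow(train))
  if (use_span) {
    n_res <- vapply(emb_train, nrow, integer(1))
    bad <- which(s0 < 0L | e0 < s0 | e0 >= n_res)
    if (length(bad) > 0L) {
      abort(paste0("Invalid span annotation for record(s): ",
                   paste(train$id[bad], collapse = ", ")))
    }
  }

  n <- nrow(train)
  steps_per_epoch <- ceiling(n / train_config$batch_size)
  total_steps <- steps_per_epoch * train_config$epochs
  warmup <- round(train_config$warmup_frac * total_steps)

  fit_log <- vector("list", train_config$epochs)
  best <- list(f1 = -Inf, epoch = NA_integer_, params = NULL)

  withr::with_seed(seed, {
    params <- .init_params(encoder$dim, config)
    state <- list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
    step <- 0L
    for (epoch in seq_len(train_config$epochs)) {
      order_idx <- sample.int(n)
      ep_class <- ep_span <- 0
      n_span_samples <- 0L
      for (b in seq_len(steps_per_epoch)) {
        batch <- order_idx[((b - 1L) * train_config$batch_size + 1L):
                             min(b * train_config$batch_size, n)]
        acc_class <- NULL
        acc_span <- NULL
        l_class_sum <- 0; l_span_sum <- 0; n_span <- 0L
        for (i in batch) {
          res <- .sample_grads(emb_train[[i]], label_idx[i], s0[i], e0[i],
                               params, config, w_sample[i], use_span,
                               config$dropout)
          l_class_sum <- l_class_sum + res$l_class
          acc_class <- .accumulate(acc_class, list(head = res$grads$head))
          if (use_span && !is.na(res$l_span)) {
            l_span_sum <- l_span_sum + res$l_span
            n_span <- n_span + 1L
            acc_span <- .accumulate(
              acc_span, list(W_span = res$grads$W_span, b_span = res$grads$b_span))
          }
        }
        nb <- length(batch)
        grads <- .zeros_like(params)
        gc_scaled <- .scale_grads(acc_class, config$w_class / nb)
        grads$head <- gc_scaled$head
        if (!is.null(acc_span) && n_span > 0L) {
          gs_scaled <- .scale_grads(acc_span, config$w_span / n_span)
          grads$W_span <- gs_scaled$W_span
          grads$b_span <- gs_scaled$b_span
        }
        step <- step + 1L
        state$t <- step
        lr <- .cosine_lr(step, total_steps, warmup, train_config$learning_rate)
        upd <- .adamw_step(params, grads, state, lr, train_config)
        params <- upd$params
        state <- upd$state
        state$t <- step
        ep_class <- ep_class + l_class_sum
        ep_span <- ep_span + l_span_sum
        n_span_samples <- n_span_samples + n_span
      }
      l_class_ep <- ep_class / n
      l_span_ep <- if (n_span_samples > 0L) ep_span / n_span_samples else NA_real_
      total_ep <- if (is.na(l_span_ep)) l_class_ep else
        config$w_class * l_class_ep + config$w_span * l_span_ep
      val <- .validation_metrics(validation, encoder, config, params, classes,
                                 weights)
      if (is.nan(val$f1_mw) || is.na(val$f1_mw)) {
        abort("Validation metric is not a number; training diverged.",
              class = "spinr_training_diverged")
      }
      fit_log[[epoch]] <- tibble(
        epoch = epoch, l_class = l_class_ep, l_span = l_span_ep,
        l_total = total_ep, val_f1_mw = val$f1_mw, val_acc_w = val$acc_w,
        lr = lr
      )
      if (val$f1_mw > best$f1) {
        best <- list(f1 = val$f1_mw, epoch = epoch, params = params)
      }
    }
  })

  structure(
    list(
      params = best$params, best_epoch = best$epoch,
      config = config, train_config = train_config,
      classes = classes, class_weights = weights,
      log = dplyr::bind_rows(fit_log),
      encoder = encoder, trained_with_spans = use_span,
      temperature = NULL, calibration = NULL, seed = as.integer(seed)
    ),
    class = "spin_fit"
  )
}

.validation_metrics <- function(validation, encoder, config, params, classes,
                                weights) {
  emb <- .embed_records(validation, encoder, config, strict = TRUE)
  pred <- vapply(
    emb,
    function(E) .forward_one(E, params, config$use_span_predictor)$predicted_class,
    integer(1)
  )
  counts <- confusion_counts(as.character(validation$label), classes[pred],
                             classes = classes)
  list(
    f1_mw = macro_weighted_f1(counts, weights),
    acc_w = weighted_accuracy(counts, weights)
  )
}

#' Predict functional classes for new sequences
#'
#' Runs the stored forward path (span prediction, pooling,
#' classification) over `new_data`, applying the calibration temperature
#' if one has been fitted.
#'
#' @param object A `spin_fit`.
#' @param new_data Tibble with `id` and `sequence` columns (extra columns
#'   are ignored here and preserved by [write_predictions()]).
#' @param temperature Override the stored temperature (`NULL` uses it).
#' @param ... Unused.
#' @return The [spin_forward()] prediction tibble.
#' @export
predict.spin_fit <- function(object, new_data, temperature = NULL, ...) {
  spin_forward(
    new_data, object$encoder, object$config, object$params,
    temperature = temperature %||% object$temperature,
    classes = object$classes
  )
}

#' @export
print.spin_fit <- function(x, ...) {
  cat(sprintf(
    "<spin_fit> %d classes, span predictor %s\n  best epoch %d (validation F1m-w %.4f), seed %d%s\n",
    x$config$n_classes, if (x$config$use_span_predictor) "on" else "off",
    x$best_epoch, max(x$log$val_f1_mw), x$seed,
    if (!is.null(x$temperature)) sprintf(", T = %.3f", x$temperature) else ""
  ))
  invisible(x)
}

#' Repeat training across several seeds
#'
#' Runs [spin_train()] once per seed and summarizes the validation
#' metrics of the selected checkpoints as mean and standard deviation
#' across runs.
#'
#' @inheritParams spin_train
#' @param seeds Integer seeds; defaults to the three in `train_config`.
#' @return A list with `fits` (one `spin_fit` per seed) and `summary`
#'   (tibble of per-seed best validation metrics plus mean/sd rows).
#' @export
spin_train_seeds <- function(train, validation, encoder, config,
                             train_config = spin_train_config(),
                             seeds = train_config$seeds) {
  fits <- purrr::map(seeds, function(s) {
    spin_train(train, validation, encoder, config, train_config, seed = s)
  })
  per_seed <- purrr::map2_dfr(fits, seeds, function(f, s) {
    row <- f$log[f$best_epoch, ]
    tibble(seed = s, best_epoch = f$best_epoch,
           val_f1_mw = row$val_f1_mw, val_acc_w = row$val_acc_w)
  })
  summary <- tibble(
    metric = c("val_f1_mw", "val_acc_w"),
    mean = c(mean(per_seed$val_f1_mw), mean(per_seed$val_acc_w)),
    sd = c(sd(per_seed$val_f1_mw), sd(per_seed$val_acc_w))
  )
  list(fits = fits, per_seed = per_seed, summary = summary)
}
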