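# CSV dialect: comma-delimited with a header row and columns
# id, sequence[, start, end][, label]. Spans are 1-based inclusive residue
# positions; the span columns must be present or absent table-wide.

.valid_letters <- paste0("^[", "ACDEFGHIKLMNPQRSTVWYX", "]+$")

#' Read a training/evaluation table
#'
#' Reads the package's CSV dialect and validates every row: unique ids,
#' sequences over the 20 canonical letters plus the ambiguity letter `X`
#' (lowercase is uppercased), and — when the optional `start`/`end` pair
#' is present — integer spans with `1 <= start <= end <= nchar(sequence)`.
#' Malformed rows abort with diagnostics naming the offending data rows;
#' nothing is skipped silently.
#'
#' @param path Path to a CSV file with columns `id`, `sequence`, optional
#'   `start` and `end` (both or neither), optional `label`.
#' @return A tibble of validated records; absent span/label columns are
#'   filled with `NA` so downstream code can test for them uniformly.
#' @export
read_training_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(c("id", "sequence"), names(tbl))
  if (length(missing) > 0L) {
    abort(paste0("Missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "spinr_schema_error")
  }
  span_cols <- c("start", "end") %in% names(tbl)
  if (xor(span_cols[1], span_cols[2])) {
    abort("Span columns must be present as a pair (`start` and `end`) or absent.",
          class = "spinr_schema_error")
  }
  has_span <- all(span_cols)
  if (!has_span) tbl$start <- tbl$end <- NA_character_
  if (!"label" %in% names(tbl)) tbl$label <- NA_character_

  tbl$sequence <- toupper(tbl$sequence)
  problems <- character(0)
  flag <- function(rows, what) {
    if (length(rows) > 0L) {
      problems <<- c(problems, sprintf("row %d: %s", rows, what))
    }
  }
  flag(which(duplicated(tbl$id)), "duplicate id")
  flag(which(is.na(tbl$sequence) | !grepl(.valid_letters, tbl$sequence)),
       "sequence empty or containing letters outside the amino-acid alphabet")
  if (has_span) {
    start <- suppressWarnings(as.integer(tbl$start))
    end <- suppressWarnings(as.integer(tbl$end))
    flag(which(is.na(start) | is.na(end)), "non-integer or missing span bound")
    len <- nchar(tbl$sequence)
    bad_order <- which(!is.na(start) & !is.na(end) &
                         (start < 1L | start > end | end > len))
    flag(bad_order, "span violates 1 <= start <= end <= sequence length")
    tbl$start <- start
    tbl$end <- end
  } else {
    tbl$start <- NA_integer_
    tbl$end <- NA_integer_
  }
  if (length(problems) > 0L) {
    abort(paste0("Malformed rows in ", path, ":\n  ",
                 paste(sort(problems), collapse = "\n  ")),
          class = "spinr_row_error")
  }
  dplyr::select(tbl, "id", "sequence", "start", "end", "label",
                dplyr::everything())
}

#' Read sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into the record dialect. The
#' id is the first whitespace-delimited token of each header; residues
#' are uppercased; spans and labels are absent, so FASTA input serves
#' inference only. Duplicate ids are disambiguated with a numeric suffix
#' and a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with `id`, `sequence`, and `NA` `start`/`end`/`label`
#'   columns.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("Cannot read FASTA file ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file ", path, " contains no sequences."))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids) > 0L) {
    warn("Duplicate FASTA ids; appending numeric suffixes to disambiguate.")
    dup <- ave(seq_along(ids), ids, FUN = seq_along)
    ids <- ifelse(dup > 1L, paste0(ids, "_", dup), ids)
  }
  tibble(
    id = ids,
    sequence = unname(toupper(as.character(set))),
    start = NA_integer_, end = NA_integer_, label = NA_character_
  )
}

#' Write predictions alongside their input records
#'
#' For CSV-style input the original columns are preserved and two columns
#' are appended: the predicted class and its probability score (fixed at
#' six decimals so files are deterministic). For FASTA or raw-list input
#' a minimal table of id, predicted class, probability, and predicted
#' span boundaries is written. Written files round-trip through
#' [readr::read_csv()].
#'
#' @param records The input records tibble (aligned row-for-row with
#'   `predictions`).
#' @param predictions Prediction tibble from [predict.spin_fit()].
#' @param path Output CSV path.
#' @param format `"csv"` to preserve the input columns, `"minimal"` for
#'   the id/class/probability/span table used for FASTA and list input.
#' @return Invisibly, the tibble that was written.
#' @export
write_predictions <- function(records, predictions, path,
                              format = c("csv", "minimal")) {
  format <- match.arg(format)
  if (nrow(records) != nrow(predictions) ||
      !identical(records$id, predictions$id)) {
    abort("`records` and `predictions` must align row-for-row.")
  }
  prob_chr <- sprintf("%.6f", predictions$probability)
  prob_chr[is.na(predictions$probability)] <- NA_character_
  out <- if (format == "csv") {
    dplyr::bind_cols(
      records,
      tibble(predicted_class = predictions$predicted_class,
             probability = prob_chr)
    )
  } else {
    tibble(
      id = records$id,
      predicted_class = predictions$predicted_class,
      probability = prob_chr,
      span_start = predictions$span_start,
      span_end = predictions$span_end
    )
  }
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) abort(paste0("Cannot write predictions to ", path,
                                     ": ", conditionMessage(e)))
  )
  invisible(out)
}

.checkpoint_version <- "1.0"

.mat_to_list <- function(m) list(dim = dim(m), data = as.numeric(m))
.list_to_mat <- function(l) matrix(l$data, nrow = l$dim[1], ncol = l$dim[2])

#' Save / load a model checkpoint
#'
#' Checkpoints are versioned JSON text bundling the head parameters, the
#' model and training configurations (including the class count and
#' labels, so inference needs no access to the training data), the class
#' weights, the training log, the calibration temperature if fitted, and
#' the encoder's name. Numbers are written with 17 significant digits,
#' so a reloaded checkpoint reproduces forward outputs bit-identically.
#'
#' @param fit A `spin_fit`.
#' @param path Destination file.
#' @return `save_checkpoint()` invisibly returns `path`;
#'   `load_checkpoint()` returns a `spin_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "spin_fit"))
  payload <- list(
    version = .checkpoint_version,
    config = unclass(fit$config),
    train_config = unclass(fit$train_config),
    classes = fit$classes,
    class_weights = as.list(fit$class_weights),
    params = list(
      W_span = .mat_to_list(fit$params$W_span),
      b_span = fit$params$b_span,
      W1 = .mat_to_list(fit$params$head$W1), b1 = fit$params$head$b1,
      W2 = .mat_to_list(fit$params$head$W2), b2 = fit$params$head$b2
    ),
    best_epoch = fit$best_epoch,
    log = fit$log,
    encoder_name = fit$encoder$name,
    encoder_dim = fit$encoder$dim,
    trained_with_spans = fit$trained_with_spans,
    temperature = fit$temperature,
    seed = fit$seed
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @param path Path to a checkpoint written by [save_checkpoint()].
#' @param encoder Optional encoder to attach; required when the stored
#'   encoder name is not reconstructible (i.e. not the toy family).
#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, encoder = NULL) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$version, .checkpoint_version)) {
    abort(sprintf(
      "Checkpoint version '%s' is incompatible with this package (expects '%s').",
      payload$version %||% "<missing>", .checkpoint_version
    ), class = "spinr_checkpoint_version")
  }
  cfg <- payload$config
  config <- spin_config(
    n_classes = cfg$n_classes, max_length = cfg$max_length,
    hidden_dim = cfg$hidden_dim, classifier_hidden = cfg$classifier_hidden,
    n_frozen_layers = cfg$n_frozen_layers, dropout = cfg$dropout,
    w_class = cfg$w_class, w_span = cfg$w_span,
    use_span_predictor = cfg$use_span_predictor
  )
  # the span predictor is active at inference iff the model was trained
  # with span annotations
  config$use_span_predictor <- isTRUE(payload$trained_with_spans)
  params <- list(
    W_span = .list_to_mat(payload$params$W_span),
    b_span = as.numeric(payload$params$b_span),
    head = list(
      W1 = .list_to_mat(payload$params$W1),
      b1 = as.numeric(payload$params$b1),
      W2 = .list_to_mat(payload$params$W2),
      b2 = as.numeric(payload$params$b2)
    )
  )
  classes <- as.character(payload$classes)
  if (length(classes) != config$n_classes ||
      length(params$head$b2) != config$n_classes ||
      ncol(params$head$W2) != config$n_classes) {
    abort("Checkpoint is internally inconsistent: `n_classes` does not match the stored classes/parameters.",
          class = "spinr_checkpoint_consistency")
  }
  encoder <- encoder %||% .encoder_from_name(payload$encoder_name)
  if (is.null(encoder)) {
    abort(sprintf(
      "Encoder '%s' cannot be reconstructed; pass it via the `encoder` argument.",
      payload$encoder_name
    ))
  }
  if (encoder$dim != payload$encoder_dim) {
    abort("Supplied encoder dimension does not match the checkpoint.",
          class = "spinr_checkpoint_consistency")
  }
  tc <- payload$train_config
  structure(
    list(
      params = params, best_epoch = payload$best_epoch,
      config = config,
      train_config = spin_train_config(
        learning_rate = tc$learning_rate, weight_decay = tc$weight_decay,
        epochs = tc$epochs, batch_size = tc$batch_size,
        eval_batch_size = tc$eval_batch_size, warmup_frac = tc$warmup_frac,
        beta1 = tc$beta1, beta2 = tc$beta2, eps = tc$eps, seeds = tc$seeds
      ),
      classes = classes,
      class_weights = setNames(unlist(payload$class_weights), classes),
      log = as_tibble(payload$log),
      encoder = encoder,
      trained_with_spans = isTRUE(payload$trained_with_spans),
      temperature = payload$temperature,
      calibration = NULL,
      seed = payload$seed
    ),
    class = "spin_fit"
  )
}
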