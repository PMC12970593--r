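# Shared fixtures. The trained synthetic models are expensive (~10 s each),
# so they are built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# Study conditions for the synthetic recovery experiments: 3 classes,
# 200 sequences/class, motif noise 0.05. Heads are trained from random
# initialization, hence the from-scratch learning rate.
synth_train_config <- function() spin_train_config(learning_rate = 2e-2)

synth_fixture <- function() {
  if (!is.null(.fixture_env$fx)) {
    return(.fixture_env$fx)
  }
  spec <- family_spec(n_classes = 3, n_per_class = 200, noise = 0.05, seed = 1)
  fam <- generate_family(spec)
  parts <- split_dataset(fam, seed = 1)
  enc <- toy_encoder()
  tc <- synth_train_config()
  fit <- spin_train(parts$train, parts$validation, enc,
                    spin_config(n_classes = 3, hidden_dim = enc$dim),
                    tc, seed = 1)
  nospan_train <- dplyr::mutate(parts$train,
                                start = NA_integer_, end = NA_integer_)
  fit_nospan <- spin_train(nospan_train, parts$validation, enc,
                           spin_config(n_classes = 3, hidden_dim = enc$dim,
                                       use_span_predictor = FALSE),
                           tc, seed = 1)
  .fixture_env$fx <- list(
    spec = spec, fam = fam, parts = parts, encoder = enc,
    train_config = tc, fit = fit, fit_nospan = fit_nospan
  )
  .fixture_env$fx
}

# A small labeled family for fast I/O and training-mechanics tests.
tiny_family <- function(seed = 3, n_per_class = 30) {
  generate_family(family_spec(
    n_classes = 2, n_per_class = n_per_class, noise = 0.05,
    domain_length = c(30L, 36L), flank_length = c(5L, 15L),
    motif_length = 7L, seed = seed
  ))
}

random_sequences <- function(n, min_len = 5, max_len = 60, seed = 99) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   sample(min_len:max_len, 1), replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

sorted_letters <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(sort(ch), collapse = ""), "")
}
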