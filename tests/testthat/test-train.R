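test_that("splits are deterministic, disjoint, exhaustive, and sized by cumulative-floor", {
  fam <- tiny_family()
  s1 <- split_dataset(fam, seed = 5)
  s2 <- split_dataset(fam, seed = 5)
  expect_identical(s1, s2)
  ids <- c(s1$train$id, s1$validation$id, s1$test$id)
  expect_setequal(ids, fam$id)
  expect_equal(length(ids), nrow(fam))

  # the published 28,151-sequence partition: 22,520 / 2,815 / 2,816
  big <- tibble::tibble(id = as.character(1:28151), sequence = "A",
                        label = "x")
  sizes <- vapply(split_dataset(big, seed = 1, stratified = FALSE), nrow,
                  integer(1))
  expect_equal(unname(sizes), c(22520L, 2815L, 2816L))
})

test_that("stratified splits preserve class proportions and flag tiny classes", {
  fam <- generate_family(family_spec(n_classes = 2, n_per_class = 500,
                                     seed = 2,
                                     domain_length = c(30L, 34L),
                                     flank_length = c(3L, 8L)))
  parts <- split_dataset(fam, seed = 3, stratified = TRUE)
  for (p in parts) {
    counts <- table(p$label)
    expect_lte(abs(counts[1] - counts[2]), 1)
  }

  small <- tibble::tibble(id = c("a", "b", "c"), sequence = "ACD",
                          label = c("x", "x", "y"))
  expect_error(split_dataset(small, stratified = TRUE),
               class = "spinr_stratification_error")
})

test_that("training is bit-reproducible given a seed", {
  fam <- tiny_family()
  parts <- split_dataset(fam, seed = 4)
  enc <- toy_encoder()
  cfg <- spin_config(n_classes = 2, hidden_dim = enc$dim)
  tc <- spin_train_config(learning_rate = 2e-2, epochs = 3)
  f1 <- spin_train(parts$train, parts$validation, enc, cfg, tc, seed = 6)
  f2 <- spin_train(parts$train, parts$validation, enc, cfg, tc, seed = 6)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
  f3 <- spin_train(parts$train, parts$validation, enc, cfg, tc, seed = 7)
  expect_false(identical(f3$log, f1$log))
})

test_that("a vanishing learning rate leaves the model and metrics frozen", {
  fam <- tiny_family()
  parts <- split_dataset(fam, seed = 4)
  enc <- toy_encoder()
  cfg <- spin_config(n_classes = 2, hidden_dim = enc$dim, dropout = 0)
  tc <- spin_train_config(learning_rate = 1e-12, epochs = 3)
  fit <- spin_train(parts$train, parts$validation, enc, cfg, tc, seed = 6)
  expect_equal(length(unique(fit$log$val_f1_mw)), 1L)
  expect_lt(max(abs(fit$log$l_class - fit$log$l_class[1])), 1e-6)
})

test_that("training without span annotations drops the span term and module", {
  fam <- dplyr::mutate(tiny_family(), start = NA_integer_, end = NA_integer_)
  parts <- split_dataset(fam, seed = 4)
  enc <- toy_encoder()
  cfg <- spin_config(n_classes = 2, hidden_dim = enc$dim)
  fit <- spin_train(parts$train, parts$validation, enc, cfg,
                    spin_train_config(learning_rate = 2e-2, epochs = 2),
                    seed = 1)
  expect_false(fit$config$use_span_predictor)
  expect_true(all(is.na(fit$log$l_span)))
  expect_equal(fit$log$l_total, fit$log$l_class)
})

test_that("checkpoint selection takes the best validation F1, earliest on ties", {
  fx <- synth_fixture()
  best <- fx$fit$best_epoch
  expect_equal(fx$fit$log$val_f1_mw[best], max(fx$fit$log$val_f1_mw))
  expect_false(any(fx$fit$log$val_f1_mw[seq_len(best - 1)] >=
                     fx$fit$log$val_f1_mw[best]))
})

test_that("the multi-seed driver reports per-seed metrics with mean and sd", {
  fam <- tiny_family()
  parts <- split_dataset(fam, seed = 4)
  enc <- toy_encoder()
  cfg <- spin_config(n_classes = 2, hidden_dim = enc$dim)
  runs <- spin_train_seeds(parts$train, parts$validation, enc, cfg,
                           spin_train_config(learning_rate = 2e-2, epochs = 2),
                           seeds = c(1, 2))
  expect_length(runs$fits, 2)
  expect_equal(nrow(runs$per_seed), 2)
  expect_equal(runs$summary$mean[1], mean(runs$per_seed$val_f1_mw))
  expect_equal(runs$summary$sd[1], sd(runs$per_seed$val_f1_mw))
})

test_that("tidiers expose the training log and a one-row summary", {
  fx <- synth_fixture()
  td <- tidy(fx$fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), fx$fit$train_config$epochs)
  gl <- glance(fx$fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$best_epoch, fx$fit$best_epoch)
})
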