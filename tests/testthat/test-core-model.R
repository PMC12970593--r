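test_that("predict_span takes per-column argmaxes with ties to the lowest index", {
  lg <- matrix(0, 30, 2)
  lg[6, 1] <- 5    # start at 0-based index 5
  lg[21, 2] <- 5   # end at 0-based index 20
  sp <- predict_span(lg)
  expect_equal(sp$t_start, 5L)
  expect_equal(sp$t_end, 20L)
  expect_false(sp$fallback)

  tie <- matrix(0, 10, 2)
  tie[c(4, 8), 1] <- 3  # equal start maxima at indices 3 and 7
  tie[10, 2] <- 3
  expect_equal(predict_span(tie)$t_start, 3L)
})

test_that("an end at or before the start falls back to the whole residue range", {
  lg <- matrix(0, 30, 2)
  lg[21, 1] <- 5   # start argmax at 20
  lg[6, 2] <- 5    # end argmax at 5
  sp <- predict_span(lg)
  expect_true(sp$fallback)
  expect_equal(sp$t_start, 0L)
  expect_equal(sp$t_end, 29L)

  eq <- matrix(0, 10, 2)
  eq[4, 1] <- eq[4, 2] <- 2  # same position for both heads
  expect_true(predict_span(eq)$fallback)
})

test_that("fully masked logits raise a degenerate-logits error", {
  lg <- matrix(-Inf, 5, 2)
  expect_error(predict_span(lg), class = "spinr_degenerate_logits")
})

test_that("predict_span is permutation-covariant where no fallback intervenes", {
  withr::with_seed(8, {
    checked <- 0L
    for (rep in 1:40) {
      lg <- matrix(rnorm(40), 20, 2)
      perm <- sample(20)
      sp <- predict_span(lg)
      sp_p <- predict_span(lg[perm, , drop = FALSE])
      if (!sp$fallback && !sp_p$fallback) {
        expect_equal(sp_p$t_start, which(perm == sp$t_start + 1L) - 1L)
        expect_equal(sp_p$t_end, which(perm == sp$t_end + 1L) - 1L)
        checked <- checked + 1L
      }
    }
    expect_gt(checked, 5L)
  })
})

test_that("pool_span averages the inclusive span and never sees the classification token", {
  emb <- rbind(
    rep(1000, 2),              # classification-token sentinel
    c(1, 3), c(5, 7), c(0, 2)  # residues
  )
  span <- predict_span(rbind(c(5, 0), c(0, 0), c(0, 5)))  # rows 0..2
  expect_equal(pool_span(emb, span), c(2, 4))

  one <- predict_span(rbind(c(0, 0), c(9, 0), c(0, 9)))   # rows 1..2
  expect_equal(pool_span(emb, one), colMeans(emb[3:4, ]))

  # sentinel at the classification-token row never leaks into pooling
  emb2 <- emb
  emb2[1, ] <- c(-1e9, 1e9)
  expect_equal(pool_span(emb2, span), pool_span(emb, span))
})

test_that("fallback spans and a disabled span predictor pool all residue rows", {
  emb <- rbind(rep(0, 3), matrix(seq_len(12), 4, 3))
  fb <- list(t_start = 0L, t_end = 3L, fallback = TRUE)
  expect_equal(pool_span(emb, fb), colMeans(emb[-1, ]))
  sp <- list(t_start = 1L, t_end = 2L, fallback = FALSE)
  expect_equal(pool_span(emb, sp, use_span_predictor = FALSE),
               colMeans(emb[-1, ]))
  # constant rows pool to that constant whatever the span
  cemb <- rbind(rep(9, 3), matrix(rep(c(1, 2, 3), each = 5), 5, 3))
  expect_equal(pool_span(cemb, sp), c(1, 2, 3))
})

test_that("pool_span rejects spans outside the residue rows", {
  emb <- rbind(rep(0, 2), matrix(1, 3, 2))
  expect_error(pool_span(emb, list(t_start = 0L, t_end = 5L, fallback = FALSE)))
})

test_that("classify returns normalized probabilities with closed-form values", {
  d <- 4
  head0 <- list(W1 = matrix(0, d, 3), b1 = rep(0, 3),
                W2 = matrix(0, 3, 5), b2 = rep(0, 5))
  out <- classify(rep(1, d), head0)
  expect_equal(out$probs, rep(1 / 5, 5))
  expect_equal(out$predicted_class, 1L)  # tie to lowest index

  # a head whose logits are (ln 2, 0): softmax = (2/3, 1/3)
  head2 <- list(W1 = matrix(0, d, 1), b1 = 0,
                W2 = matrix(0, 1, 2), b2 = c(log(2), 0))
  out2 <- classify(rep(0, d), head2)
  expect_equal(out2$probs, c(2 / 3, 1 / 3), tolerance = 1e-12)

  withr::with_seed(5, {
    for (i in 1:10) {
      head_r <- list(W1 = matrix(rnorm(d * 3), d, 3), b1 = rnorm(3),
                     W2 = matrix(rnorm(3 * 4), 3, 4), b2 = rnorm(4))
      p <- classify(rnorm(d), head_r)$probs
      expect_equal(sum(p), 1, tolerance = 1e-6)
      expect_true(all(p >= 0))
    }
  })

  bad <- list(W1 = matrix(1, d, 2), b1 = rep(0, 2),
              W2 = matrix(Inf, 2, 2), b2 = rep(0, 2))
  expect_error(classify(rep(1, d), bad), class = "spinr_numeric_error")
})

test_that("forward handles batches like singles and reports per-record failures", {
  fx <- synth_fixture()
  recs <- fx$parts$test[1:3, ]
  batch <- spin_forward(recs, fx$encoder, fx$fit$config, fx$fit$params,
                        classes = fx$fit$classes)
  singles <- dplyr::bind_rows(lapply(1:3, function(i) {
    spin_forward(recs[i, ], fx$encoder, fx$fit$config, fx$fit$params,
                 classes = fx$fit$classes)
  }))
  expect_equal(batch, singles, tolerance = 1e-12)

  mixed <- tibble::tibble(
    id = c("ok", "toolong", "empty"),
    sequence = c(recs$sequence[1], paste(rep("A", 2000), collapse = ""), "")
  )
  out <- spin_forward(mixed, fx$encoder, fx$fit$config, fx$fit$params,
                      classes = fx$fit$classes)
  expect_equal(out$status, c("ok", "excluded", "invalid"))
  expect_true(is.na(out$predicted_class[2]))
  expect_false(is.na(out$predicted_class[1]))
})

test_that("disabling the span predictor marks every prediction as full-sequence", {
  fx <- synth_fixture()
  cfg <- fx$fit$config
  cfg$use_span_predictor <- FALSE
  out <- spin_forward(fx$parts$test[1:5, ], fx$encoder, cfg, fx$fit$params,
                      classes = fx$fit$classes)
  expect_true(all(out$span_fallback))
  expect_equal(out$span_start, rep(1L, 5))
  expect_equal(out$span_end, nchar(fx$parts$test$sequence[1:5]))
})
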