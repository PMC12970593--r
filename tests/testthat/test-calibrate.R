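# Build a batch of logits that is calibrated by construction: labels are
# drawn from the softmax of the logits themselves.
calibrated_batch <- function(n, k, scale = 1, seed = 1) {
  withr::with_seed(seed, {
    logits <- matrix(rnorm(n * k, sd = 1.5), n, k)
    probs <- exp(logits) / rowSums(exp(logits))
    labels <- vapply(seq_len(n), function(i) {
      sample.int(k, 1, prob = probs[i, ])
    }, integer(1))
    list(logits = logits * scale, labels = labels)
  })
}

test_that("temperature fitting recovers the identity on calibrated logits", {
  cb <- calibrated_batch(4000, 3, scale = 1, seed = 2)
  cal <- fit_temperature(cb$logits, cb$labels)
  expect_lt(abs(cal$temperature - 1), 0.1)
})

test_that("temperature fitting recovers a known scaling factor", {
  cb <- calibrated_batch(4000, 3, scale = 3, seed = 3)
  cal <- fit_temperature(cb$logits, cb$labels)
  expect_lt(abs(cal$temperature - 3) / 3, 0.05)
  expect_lte(cal$ece_after, cal$ece_before)
})

test_that("temperature scaling never changes the predicted class", {
  withr::with_seed(11, {
    for (i in 1:20) {
      logits <- matrix(rnorm(60), 20, 3)
      labels <- sample.int(3, 20, replace = TRUE)
      cal <- fit_temperature(logits, labels)
      before <- max.col(logits, ties.method = "first")
      after <- max.col(logits / cal$temperature, ties.method = "first")
      expect_identical(before, after)
    }
  })
})

test_that("ECE matches closed forms, hand values, and its oracle", {
  sure_right <- cbind(rep(1, 10), rep(0, 10))
  expect_equal(expected_calibration_error(sure_right, rep(1L, 10)), 0)
  expect_equal(expected_calibration_error(sure_right, rep(2L, 10)), 1)

  # confidences (.95,.95,.55,.55), correctness (1,1,1,0), 10 bins:
  # bin (0.9,1]: 2/4 * |1 - .95|; bin (0.5,.6]: 2/4 * |.5 - .55| => 0.05
  probs <- rbind(c(0.95, 0.05), c(0.95, 0.05), c(0.55, 0.45), c(0.55, 0.45))
  labels <- c(1L, 1L, 1L, 2L)
  expect_equal(expected_calibration_error(probs, labels, n_bins = 10), 0.05,
               tolerance = 1e-12)
  expect_equal(
    expected_calibration_error(probs, labels, n_bins = 10),
    oracle_ece(c(0.95, 0.95, 0.55, 0.55), c(TRUE, TRUE, TRUE, FALSE), 10),
    tolerance = 1e-12
  )

  withr::with_seed(6, {
    for (i in 1:20) {
      raw <- matrix(runif(30 * 3), 30, 3)
      p <- raw / rowSums(raw)
      lab <- sample.int(3, 30, replace = TRUE)
      e <- expected_calibration_error(p, lab)
      expect_gte(e, 0)
      expect_lte(e, 1)
      expect_equal(e, oracle_ece(apply(p, 1, max),
                                 max.col(p, ties.method = "first") == lab, 10),
                   tolerance = 1e-12)
    }
  })
})

test_that("a perfectly calibrated binary set has near-zero ECE", {
  withr::with_seed(12, {
    conf <- runif(4000, 0.5, 1)
    correct <- runif(4000) < conf
    probs <- cbind(conf, 1 - conf)
    labels <- ifelse(correct, 1L, 2L)
    expect_lt(expected_calibration_error(probs, labels), 0.03)
  })
})

test_that("abstention thresholds behave as documented", {
  probs <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  out <- classify_with_abstention(probs, 0.8, classes = c("a", "b"))
  expect_equal(out$label, c("a", "UNKNOWN"))

  never <- classify_with_abstention(probs, 0, classes = c("a", "b"))
  expect_false(any(never$label == "UNKNOWN"))

  withr::with_seed(14, {
    raw <- matrix(runif(50 * 3), 50, 3)
    p <- raw / rowSums(raw)
    fracs <- vapply(seq(0, 1, by = 0.05), function(t) {
      mean(classify_with_abstention(p, t)$label == "UNKNOWN")
    }, numeric(1))
    expect_true(all(diff(fracs) >= 0))
  })
})

test_that("confidence distributions locate a separating crossing point", {
  withr::with_seed(15, {
    conf_in <- runif(300, 0.9, 1)
    conf_out <- runif(300, 0.1, 0.5)
    cd <- confidence_distributions(conf_in, conf_out)
    expect_gt(cd$threshold, 0.5)
    expect_lt(cd$threshold, 0.9)

    expect_warning(confidence_distributions(conf_in, conf_in),
                   class = "spinr_no_separation")

    # skewed beta-distributed confidences: crossing matches the oracle scan
    a <- rbeta(2000, 8, 2)
    b <- rbeta(2000, 2, 8)
    cd2 <- confidence_distributions(a, b, n_bins = 20)
    expect_equal(cd2$threshold, oracle_crossing(a, b, 20), tolerance = 1e-12)
  })
})
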