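test_that("confusion counts tally one-vs-rest outcomes", {
  all_right <- confusion_counts(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  expect_true(all(all_right$fp == 0) && all(all_right$fn == 0))
  expect_equal(sum(all_right$tp), 10)

  tallied <- confusion_counts(c("A", "B", "B"), c("A", "A", "B"))
  a <- tallied[tallied$class == "A", ]
  expect_equal(c(a$tp, a$fp, a$fn, a$tn), c(1, 1, 0, 1))

  solo <- confusion_counts(rep("only", 4), rep("only", 4))
  expect_equal(c(solo$tp, solo$fp, solo$fn, solo$tn), c(4, 0, 0, 0))

  expect_error(confusion_counts(c("a", "b"), "a"))
})

test_that("perfect predictions score 1 and absent classes contribute F1 = 0", {
  truth <- rep(c("a", "b", "c"), c(5, 3, 2))
  counts <- confusion_counts(truth, truth)
  w <- compute_class_weights(truth)
  expect_equal(macro_weighted_f1(counts, w), 1)
  expect_equal(weighted_accuracy(counts, w), 1)

  # class "c" neither predicted nor true in this split, but in the class set
  counts3 <- confusion_counts(c("a", "a", "b"), c("a", "a", "b"),
                              classes = c("a", "b", "c"))
  w3 <- setNames(c(1, 1, 1), c("a", "b", "c"))
  expect_equal(macro_weighted_f1(counts3, w3), 2 / 3, tolerance = 1e-12)
})

test_that("both metrics agree with brute-force oracles on random instances", {
  withr::with_seed(31, {
    for (i in 1:200) {
      k <- sample(2:6, 1)
      classes <- letters[seq_len(k)]
      n_train <- sample(20:100, 1)
      train_labels <- c(classes, sample(classes, n_train - k, replace = TRUE))
      n <- sample(5:60, 1)
      truth <- sample(classes, n, replace = TRUE)
      estimate <- sample(classes, n, replace = TRUE)
      counts <- confusion_counts(truth, estimate, classes)
      w <- compute_class_weights(train_labels, classes)
      oracle <- oracle_metrics(truth, estimate, classes, train_labels)
      expect_equal(macro_weighted_f1(counts, w), oracle$f1_mw,
                   tolerance = 1e-12)
      expect_equal(weighted_accuracy(counts, w), oracle$acc_w,
                   tolerance = 1e-12)
      expect_equal(weighted_accuracy(counts, w, normalize = "classes"),
                   oracle$acc_w_classes, tolerance = 1e-12)
    }
  })
})

test_that("with balanced supports the weighted metrics equal their unweighted forms", {
  withr::with_seed(17, {
    for (i in 1:50) {
      k <- sample(2:5, 1)
      classes <- letters[seq_len(k)]
      per <- sample(5:20, 1)
      train_labels <- rep(classes, each = per)
      truth <- sample(classes, 40, replace = TRUE)
      estimate <- sample(classes, 40, replace = TRUE)
      counts <- confusion_counts(truth, estimate, classes)
      w <- compute_class_weights(train_labels, classes)
      expect_equal(unname(w), rep(1, k))
      f1_unw <- mean(ifelse(2 * counts$tp + counts$fp + counts$fn == 0, 0,
                            2 * counts$tp / (2 * counts$tp + counts$fp + counts$fn)))
      expect_equal(macro_weighted_f1(counts, w), f1_unw, tolerance = 1e-12)
      expect_equal(weighted_accuracy(counts, w),
                   weighted_accuracy(counts, w, normalize = "classes"),
                   tolerance = 1e-12)
    }
  })
})

test_that("metrics are invariant to class relabeling", {
  withr::with_seed(13, {
    for (i in 1:25) {
      classes <- c("a", "b", "c")
      train_labels <- c(classes, sample(classes, 47, replace = TRUE))
      truth <- sample(classes, 30, replace = TRUE)
      estimate <- sample(classes, 30, replace = TRUE)
      relab <- c(a = "z2", b = "z3", c = "z1")
      w <- compute_class_weights(train_labels, classes)
      w2 <- compute_class_weights(unname(relab[train_labels]), sort(relab))
      m1 <- macro_weighted_f1(confusion_counts(truth, estimate, classes), w)
      m2 <- macro_weighted_f1(
        confusion_counts(relab[truth], relab[estimate], sort(relab)), w2)
      expect_equal(m1, m2, tolerance = 1e-12)
      a1 <- weighted_accuracy(confusion_counts(truth, estimate, classes), w)
      a2 <- weighted_accuracy(
        confusion_counts(relab[truth], relab[estimate], sort(relab)), w2)
      expect_equal(a1, a2, tolerance = 1e-12)
    }
  })
})

test_that("span accuracy applies the tolerance boundary-wise", {
  sa <- span_accuracy(pred_start = c(10, 10), true_start = c(13, 14),
                      pred_end = c(50, 50), true_end = c(50, 47),
                      tolerance = 3)
  expect_equal(sa$accuracy[sa$boundary == "start"], 0.5)  # |10-13| in, |10-14| out
  expect_equal(sa$accuracy[sa$boundary == "end"], 1.0)

  exact <- span_accuracy(c(10, 11), c(10, 12), c(20, 20), c(20, 20),
                         tolerance = 0)
  expect_equal(exact$accuracy[exact$boundary == "start"], 0.5)

  # monotone non-decreasing in tolerance
  withr::with_seed(4, {
    ps <- sample(1:50, 30, replace = TRUE); ts <- sample(1:50, 30, replace = TRUE)
    pe <- sample(1:50, 30, replace = TRUE); te <- sample(1:50, 30, replace = TRUE)
    accs <- vapply(0:10, function(tol) {
      span_accuracy(ps, ts, pe, te, tol)$accuracy[1]
    }, numeric(1))
    expect_true(all(diff(accs) >= 0))
  })
})

test_that("bootstrap CIs are deterministic, ordered, and degenerate when all pairs hit", {
  ci <- bootstrap_span_ci(pred_start = 1:20, true_start = 1:20,
                          pred_end = 21:40, true_end = 21:40,
                          n_boot = 200, seed = 9)
  expect_equal(ci$mean, c(1, 1))
  expect_equal(ci$ci_low, c(1, 1))
  expect_equal(ci$ci_high, c(1, 1))

  ps <- c(1, 2, 30, 4, 5, 60, 7, 8)
  ci1 <- bootstrap_span_ci(ps, 1:8, ps, 1:8, n_boot = 300, seed = 7)
  ci2 <- bootstrap_span_ci(ps, 1:8, ps, 1:8, n_boot = 300, seed = 7)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$ci_low <= ci1$mean & ci1$mean <= ci1$ci_high))

  expect_error(bootstrap_span_ci(1, 1, 1, 1))
})
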