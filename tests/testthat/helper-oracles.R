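# Independent brute-force oracles, written against the printed formulas
# with plain loops; they share no code with the package implementations.

oracle_metrics <- function(truth, estimate, classes, n_train_labels) {
  n <- length(truth)
  k <- length(classes)
  support <- vapply(classes, function(cl) sum(n_train_labels == cl), numeric(1))
  w <- length(n_train_labels) / (k * support)
  f1 <- acc <- numeric(k)
  for (i in seq_len(k)) {
    cl <- classes[i]
    tp <- fp <- fn <- tn <- 0
    for (j in seq_len(n)) {
      if (truth[j] == cl && estimate[j] == cl) tp <- tp + 1
      if (truth[j] != cl && estimate[j] == cl) fp <- fp + 1
      if (truth[j] == cl && estimate[j] != cl) fn <- fn + 1
      if (truth[j] != cl && estimate[j] != cl) tn <- tn + 1
    }
    f1[i] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    acc[i] <- (tp + tn) / n
  }
  list(
    f1_mw = sum(w * f1) / sum(w),
    acc_w = sum(w * acc) / sum(w),
    acc_w_classes = sum(w * acc) / k
  )
}

oracle_ece <- function(conf, correct, n_bins) {
  n <- length(conf)
  total <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins
    hi <- b / n_bins
    members <- which(conf > lo & conf <= hi | (b == 1 & conf <= lo + 1e-15))
    if (length(members) == 0) next
    gap <- abs(mean(correct[members]) - mean(conf[members]))
    total <- total + length(members) / n * gap
  }
  total
}

# Density-intersection scan on a fine grid of candidate thresholds;
# returns the lowest point where the binned density difference flips sign.
oracle_crossing <- function(conf_in, conf_out, n_bins) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  d_in <- graphics::hist(conf_in, breaks = breaks, plot = FALSE)$density
  d_out <- graphics::hist(conf_out, breaks = breaks, plot = FALSE)$density
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  sgn <- sign(d_in - d_out)
  nz <- which(sgn != 0)
  if (length(nz) < 2) return(NA_real_)
  for (k in 2:length(nz)) {
    if (sgn[nz[k]] != sgn[nz[k - 1]]) {
      return((mids[nz[k - 1]] + mids[nz[k]]) / 2)
    }
  }
  NA_real_
}
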