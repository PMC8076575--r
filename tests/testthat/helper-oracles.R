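# Independent reference implementations used as test oracles. These are
# deliberately naive, direct translations of the definitions, kept free of
# any code shared with the package internals.

# Cry-sequence detection by direct quantifier checks (1-based internally,
# 0-based output like detect_sequences).
brute_sequences_r <- function(labels, start_min_cry, start_window, stop_gap) {
  n <- length(labels)
  seqs <- list()
  prev_end <- 0L # 1-based index of the last epoch inside any sequence
  a <- 1L
  while (a + start_window - 1L <= n) {
    if (a <= prev_end) {
      a <- a + 1L
      next
    }
    win <- labels[a:(a + start_window - 1L)]
    if (sum(win) >= start_min_cry) {
      start <- a + which(win == 1L)[1L] - 1L
      end <- start
      e <- start + 1L
      while (e <= n) {
        if (labels[e] == 1L) {
          if (e - end - 1L < stop_gap) end <- e else break
        }
        e <- e + 1L
      }
      seqs[[length(seqs) + 1L]] <- c(start, end)
      prev_end <- end
      a <- end + 1L
    } else {
      a <- a + 1L
    }
  }
  if (length(seqs) == 0L) {
    return(matrix(integer(), 0L, 2L))
  }
  do.call(rbind, seqs) - 1L
}

sequences_as_matrix <- function(seq_tbl) {
  cbind(as.integer(seq_tbl$start_epoch), as.integer(seq_tbl$end_epoch))
}

# Metric formulas re-derived from the confusion counts, one by one.
naive_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  total <- tp + fp + tn + fn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(
    accuracy = (tp + tn) / total,
    mcc = if (den > 0) (tp * tn - fp * fn) / den else 0,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    ppv = if (tp + fp > 0) tp / (tp + fp) else 0,
    npv = if (tn + fn > 0) tn / (tn + fn) else 0
  )
}

# Loop-based confusion counting.
naive_confusion <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1L && pred[i] == 1L) tp <- tp + 1L
    if (truth[i] == 0L && pred[i] == 1L) fp <- fp + 1L
    if (truth[i] == 0L && pred[i] == 0L) tn <- tn + 1L
    if (truth[i] == 1L && pred[i] == 0L) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Statistical functionals recomputed one definition at a time.
naive_functionals <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  # type-7 quantile by hand: linear interpolation of order statistics
  q7 <- function(p) {
    xs <- sort(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  c(
    mean = mu,
    sd = sqrt(m2),
    min = min(x), max = max(x), range = max(x) - min(x),
    p1 = q7(0.01), p25 = q7(0.25), p50 = q7(0.5), p75 = q7(0.75), p99 = q7(0.99),
    iqr = q7(0.75) - q7(0.25),
    skew = if (m2 > 0) m3 / m2^1.5 else 0,
    kurt = if (m2 > 0) m4 / m2^2 - 3 else 0
  )
}
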