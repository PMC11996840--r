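# Naive loop implementations used as independent oracles. These deliberately
# mirror the definitions, not the package internals.

naive_kteo <- function(x, k, rectified = FALSE) {
  n <- length(x)
  p <- numeric(n)
  for (i in seq_len(n)) {
    if (i > k && i <= n - k) {
      v <- x[i]^2 - x[i + k] * x[i - k]
      p[i] <- if (rectified) abs(v) else v
    }
  }
  p
}

naive_mteo <- function(x, k_max, rectified = FALSE) {
  n <- length(x)
  p <- numeric(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (k in seq_len(k_max)) {
      if (i > k && i <= n - k) {
        v <- x[i]^2 - x[i + k] * x[i - k]
        vals <- c(vals, if (rectified) abs(v) else v)
      }
    }
    p[i] <- if (length(vals)) max(vals) else 0
  }
  p
}

naive_median_smooth <- function(e, L) {
  n <- length(e)
  h <- (L - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1, n - i)
    out[i] <- median(sort(e[(i - hh):(i + hh)]))
  }
  out
}

# Literal definition: onset at earliest E_n with ton samples all > th1,
# offset at earliest E_m > E_n with toff samples all < th1; resume after
# E_m + toff; trailing activity closes at the last sample.
naive_double_threshold <- function(e, th1, ton, toff) {
  n <- length(e)
  all_above <- function(i, len) {
    i + len - 1 <= n && all(e[i:(i + len - 1)] > th1)
  }
  all_below <- function(i, len) {
    i + len - 1 <= n && all(e[i:(i + len - 1)] < th1)
  }
  on <- c(); off <- c()
  i <- 1
  while (i <= n) {
    en <- NA
    for (j in i:n) if (all_above(j, ton)) { en <- j; break }
    if (is.na(en) || en >= n) break
    em <- n
    if (en + 1 <= n) {
      for (j in (en + 1):n) if (all_below(j, toff)) { em <- j; break }
    }
    on <- c(on, en); off <- c(off, em)
    i <- em + toff
  }
  list(on = on, off = off)
}

# Compact labelled recording for detector tests.
tiny_recording <- function(seed, duration = 20, n_bursts = 5, ...) {
  simulate_emg(duration = duration, n_bursts = n_bursts, seed = seed, ...)
}

# Table 2 metric rows (Onset TPR %, Offset TPR %, F1 %, biases ms) with the
# printed composite scores.
table2_rows <- list(
  TEOTD   = list(m = c(85.17, 77.67, 82.53, 183, 295), score = 0.6550),
  aTEOTD  = list(m = c(90.23, 88.87, 88.29, 154, 255), score = 0.7161),
  MEOTD   = list(m = c(95.15, 92.27, 91.67, 133, 239), score = 0.7482),
  aMEOTD  = list(m = c(95.16, 92.83, 91.80, 117, 223), score = 0.7502),
  MEONND  = list(m = c(97.31, 93.33, 93.48, 103, 209), score = 0.7615),
  aMEONND = list(m = c(97.31, 93.58, 93.72, 102, 204), score = 0.7627))

row_as_metrics <- function(m) {
  list(onset_tpr = m[1] / 100, offset_tpr = m[2] / 100, f1 = m[3],
       onset_bias_ms = m[4], offset_bias_ms = m[5])
}
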