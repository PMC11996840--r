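test_that("the fixed neuron weights reproduce the lag-k energy exactly", {
  set.seed(61)
  for (k in c(1, 3, 7)) {
    x <- rnorm(50)
    ck <- conv_energy_layer(x, k)
    psi <- as.numeric(kteo(x, k))
    denom <- pmax(abs(psi), 1)
    expect_true(all(abs(ck - psi) / denom <= 1e-12))
  }
  expect_equal(conv_energy_layer(c(1, 2, 3, 4, 5), 1)[2:4], c(1, 1, 1))
  expect_equal(conv_energy_layer(rep(2, 10), 2), rep(0, 10))
})

test_that("non-canonical weights are rejected", {
  w <- network_weights()
  w$W4 <- 1
  expect_error(conv_energy_layer(rnorm(20), 1, weights = w), "fixed")
})

test_that("sampling layer stays in [0,1] with degenerate windows at 0", {
  expect_equal(minmax_normalize(rep(3, 10)), rep(0, 10))
  expect_equal(minmax_normalize(rep(3, 10), window = 4), rep(0, 10))
  set.seed(62)
  e <- abs(rnorm(300))
  for (win in list(NULL, 10L)) {
    y <- minmax_normalize(e, window = win)
    expect_true(all(y >= 0 & y <= 1))
  }
  # causal variant: strictly increasing series pins every full window to 1
  y <- minmax_normalize(1:50, window = 8)
  expect_true(all(y[2:50] == 1))
  expect_equal(y[1], 0)
  # causal brute force
  e <- rnorm(100)
  y <- minmax_normalize(e, window = 12)
  for (i in seq_along(e)) {
    w <- e[max(1, i - 11):i]
    want <- if (max(w) > min(w)) (e[i] - min(w)) / (max(w) - min(w)) else 0
    expect_equal(y[i], want)
  }
})

test_that("sigmoid hard limiter thresholds where expected", {
  expect_equal(classify_mask(0, 0.506), 0L)       # sigmoid(0) = 0.5
  expect_equal(classify_mask(1, 0.506), 1L)       # sigmoid(1) ~ 0.7311
  expect_equal(1 / (1 + exp(-1)), 0.7310586, tolerance = 1e-6)
  # T below sigmoid(0) activates everything on a [0,1] input
  set.seed(63)
  y <- runif(100)
  expect_true(all(classify_mask(y, 0.406) == 1L))
  # raising T never turns a 0 into a 1
  m1 <- classify_mask(y, 0.506)
  m2 <- classify_mask(y, 0.52)
  expect_true(all(m2 <= m1))
})

test_that("short activations are pruned, long ones and gaps are kept", {
  fs <- 1024
  min_len <- ms_to_samples(30, fs)
  expect_equal(min_len, 31L)
  m <- rep(0L, 500)
  m[100 + seq_len(20)] <- 1L              # ~20 ms: removed
  m[300 + seq_len(103)] <- 1L             # ~100 ms: kept
  out <- prune_short_runs(m, min_len)
  expect_equal(sum(out[100 + seq_len(20)]), 0)
  expect_equal(out[300 + seq_len(103)], rep(1L, 103))
  expect_equal(prune_short_runs(rep(0L, 50), min_len), rep(0L, 50))
  # gaps are never merged
  g <- c(rep(1L, 40), rep(0L, 5), rep(1L, 40))
  expect_equal(prune_short_runs(g, 31), g)
})

test_that("mask edge extraction places onsets and offsets correctly", {
  m <- rep(0L, 20); m[12:14] <- 1L
  ev <- mask_to_changepoints(m, fs = 1)
  expect_equal(ev$index, c(12L, 15L))
  expect_equal(ev$time_s, c(11, 14))
  ev2 <- mask_to_changepoints(c(0L, 1L, 1L), fs = 1) # trailing open run
  expect_equal(ev2$index, c(2L, 3L))
})

test_that("meonnd output is invariant to global amplitude scaling", {
  rec <- tiny_recording(71, duration = 15, n_bursts = 3)
  f1 <- meonnd(rec)
  f2 <- meonnd(emg_signal(rec$signal$samples * 37.5, rec$fs))
  expect_equal(f1$events$index, f2$events$index)
  f3 <- meonnd(emg_signal(rec$signal$samples * 0.01, rec$fs))
  expect_equal(f1$events$index, f3$events$index)
})

test_that("meonnd recovers bursts on clean recordings; silence yields none", {
  rec <- tiny_recording(72, duration = 30, n_bursts = 6)
  m <- evaluate_detection(meonnd(rec), rec)
  expect_equal(m$onset_tpr, 1)
  expect_lte(m$onset_bias_ms, 100)
  expect_equal(nrow(meonnd(emg_signal(rep(0, 5000), 1024))$events), 0)
})

test_that("post-processed detections contain no sub-minimum activation", {
  rec <- tiny_recording(73)
  fit <- meonnd(rec)
  r <- rle(fit$mask)
  runs1 <- r$lengths[r$values == 1]
  expect_true(all(runs1 >= ms_to_samples(30, rec$fs)))
})
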