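test_that("sinusoid generator produces exact cosine samples", {
  expect_equal(generate_sinusoid(1, pi / 2, n_samples = 4)$samples,
               c(1, 0, -1, 0))
  expect_equal(generate_sinusoid(0, 1, n_samples = 10)$samples, rep(0, 10))
})

test_that("recordings are bit-identical under a fixed seed", {
  a <- simulate_emg(duration = 12, n_bursts = 3, seed = 99)
  b <- simulate_emg(duration = 12, n_bursts = 3, seed = 99)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_emg(duration = 12, n_bursts = 3, seed = 100)
  expect_false(identical(a$signal$samples, c_$signal$samples))
})

test_that("seeded simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- rnorm(1)
  set.seed(123)
  invisible(simulate_emg(duration = 10, n_bursts = 2, seed = 7))
  expect_identical(rnorm(1), r1)
})

test_that("truth bookkeeping: alternating events, requested burst count", {
  rec <- simulate_emg(duration = 120, n_bursts = 30, seed = 4)
  expect_equal(nrow(rec$truth), 60)
  expect_equal(rec$truth$event, rep(c("onset", "offset"), 30))
  expect_true(all(diff(rec$truth$time_s) > 0))
  gaps <- rec$bursts$onset[-1] - rec$bursts$offset[-30]
  expect_true(all(gaps >= 0.6))
  durs <- rec$bursts$offset - rec$bursts$onset
  expect_true(all(durs >= 0.5 & durs <= 2))
  expect_gte(rec$bursts$onset[1], 2)
})

test_that("zero baseline sigma leaves the signal exactly zero outside bursts", {
  rec <- simulate_emg(duration = 10, n_bursts = 2, baseline_sigma = 0,
                      seed = 8)
  t <- (seq_along(rec$signal$samples) - 1) / rec$fs
  outside <- rep(TRUE, length(t))
  for (b in seq_len(nrow(rec$bursts))) {
    outside[t >= rec$bursts$onset[b] & t <= rec$bursts$offset[b]] <- FALSE
  }
  expect_true(all(rec$signal$samples[outside] == 0))
  expect_true(any(rec$signal$samples[!outside] != 0))
})

test_that("baseline sd and burst SNR match the requested levels", {
  rec <- simulate_emg(duration = 60, n_bursts = 10, baseline_sigma = 2,
                      snr_db = 20, seed = 21)
  t <- (seq_along(rec$signal$samples) - 1) / rec$fs
  base <- rep(TRUE, length(t))
  for (b in seq_len(nrow(rec$bursts))) {
    base[t >= rec$bursts$onset[b] - 0.1 & t <= rec$bursts$offset[b] + 0.1] <- FALSE
  }
  expect_gte(sum(base) / rec$fs, 10) # >= 10 s of pure baseline
  expect_equal(sd(rec$signal$samples[base]), 2, tolerance = 0.05)
  expect_equal(rec$burst_sigma, 2 * 10^(20 / 20))
})

test_that("burst spectrum concentrates inside the configured band", {
  rec <- simulate_emg(duration = 30, n_bursts = 1, baseline_sigma = 0,
                      burst_duration = c(20, 20), band = c(50, 200),
                      seed = 31)
  b <- rec$bursts
  i0 <- round((b$onset + 1) * rec$fs); i1 <- round((b$offset - 1) * rec$fs)
  seg <- rec$signal$samples[i0:i1]
  sp <- stats::spec.pgram(seg, taper = 0, plot = FALSE)
  freq_hz <- sp$freq * rec$fs
  inband <- freq_hz >= 50 & freq_hz <= 200
  expect_gte(sum(sp$spec[inband]) / sum(sp$spec), 0.90)
})

test_that("invalid burst layouts are refused", {
  expect_error(simulate_emg(duration = 5, n_bursts = 10, seed = 1),
               "cannot place")
  expect_error(simulate_emg(duration = 10, seed = 1,
                            bursts = data.frame(onset = c(1, 1.5),
                                                offset = c(2, 3))),
               "separated")
  expect_error(simulate_emg(duration = 10, band = c(20, 600), seed = 1),
               "band")
})
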