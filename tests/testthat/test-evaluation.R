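test_that("region partition matches direct interval arithmetic", {
  truth <- change_points(c("onset", "offset"), c(1.0, 2.0))
  reg <- build_regions(truth, duration = 3)
  expect_equal(reg$kind, c("baseline", "onset_segment", "activity",
                           "offset_segment", "baseline"))
  expect_equal(reg$start, c(0, 0.7, 1.2, 1.7, 2.2))
  expect_equal(reg$end, c(0.7, 1.2, 1.7, 2.2, 3))
  # empty truth: one baseline region
  reg0 <- build_regions(change_points(), duration = 5)
  expect_equal(nrow(reg0), 1)
  expect_equal(reg0$kind, "baseline")
  # short burst: segments abut, no activity region
  regs <- build_regions(change_points(c("onset", "offset"), c(1.0, 1.4)),
                        duration = 3)
  expect_false("activity" %in% regs$kind)
  on_end <- regs$end[regs$kind == "onset_segment"]
  off_start <- regs$start[regs$kind == "offset_segment"]
  expect_equal(on_end, off_start)
})

test_that("overlapping valid intervals across bursts are refused", {
  truth <- cp_from_bursts(c(1, 2.3), c(1.8, 3.2))
  expect_error(build_regions(truth, 5), "overlap")
})

test_that("event classification follows the region rules", {
  truth <- change_points(c("onset", "offset"), c(1.0, 2.0))
  reg <- build_regions(truth, duration = 4)
  score <- function(ev, tm) {
    classify_events(change_points(ev, tm), reg)
  }
  # early detection inside the onset segment is a TP; the three untargeted
  # regions (two baselines, one activity) each contribute a TN
  cl <- score(c("onset", "offset"), c(0.9, 2.05))
  expect_equal(unname(cl$counts["pooled", ]), c(2L, 3L, 0L, 0L))
  expect_equal(cl$pairs$detected_s, c(0.9, 2.05))
  # onset inside the activity region is an FP; the segment itself FNs
  cl <- score(c("onset", "offset"), c(1.4, 2.05))
  expect_equal(cl$counts["onset", "FP"], 1L)
  expect_equal(cl$counts["onset", "FN"], 1L)
  expect_equal(cl$counts["offset", "TP"], 1L)
  # nothing detected: both segments FN, both untargeted regions TN
  cl <- classify_events(change_points(), reg)
  expect_equal(unname(cl$counts["pooled", ]), c(0L, 3L, 0L, 2L))
  # multiple events in one segment score FP, not TP
  cl <- score(c("onset", "offset", "onset", "offset"),
              c(0.8, 0.9, 1.0, 2.1))
  expect_equal(cl$counts["onset", "TP"], 0L)
  expect_gte(cl$counts["onset", "FP"], 1L)
  # a lone offset inside the onset segment scores FP for the segment; the
  # stray onset in the baseline is a second (onset-typed) FP
  cl <- score(c("onset", "offset"), c(0.2, 0.9))
  expect_equal(cl$counts["onset", "TP"], 0L)
  expect_equal(cl$counts["pooled", "FP"], 2L)
  expect_equal(cl$counts["onset", "FN"], 0L)
})

test_that("events outside the recording span are dropped with a warning", {
  truth <- change_points(c("onset", "offset"), c(1.0, 2.0))
  reg <- build_regions(truth, duration = 4)
  det <- data.frame(event = c("onset", "offset"), time_s = c(0.9, 7.5))
  class(det) <- c("change_points", "data.frame")
  expect_warning(cl <- classify_events(det, reg), "outside")
  expect_equal(cl$n_detected[["offset"]], 0L)
})

test_that("classification is invariant to detected-event order", {
  truth <- cp_from_bursts(c(1, 3), c(2, 4))
  reg <- build_regions(truth, 6)
  det <- data.frame(event = c("onset", "offset", "onset", "offset"),
                    time_s = c(1.02, 2.03, 3.01, 3.99))
  class(det) <- c("change_points", "data.frame")
  shuf <- det[c(3, 1, 4, 2), ]
  expect_equal(classify_events(det, reg)$counts,
               classify_events(shuf, reg)$counts)
})

test_that("metrics reproduce the worked ratios, F1 and RMSD", {
  # 9 of 10 onsets: TPR 0.9; TP=9, FP=1, FN=1 -> F1 = 90
  truth <- cp_from_bursts(seq(1, 91, by = 10), seq(2, 92, by = 10))
  cl <- list(counts = matrix(c(9L, 0L, 1L, 1L, 0L, 0L, 0L, 0L,
                               9L, 0L, 1L, 1L),
                             nrow = 3, byrow = TRUE,
                             dimnames = list(c("onset", "offset", "pooled"),
                                             c("TP", "TN", "FP", "FN"))),
             pairs = data.frame(event = rep("onset", 2),
                                true_s = c(1, 2),
                                detected_s = c(1.1, 1.9)),
             n_detected = c(onset = 10L, offset = 0L))
  class(cl) <- "confusion_counts"
  m <- compute_metrics(cl, truth)
  expect_equal(m$onset_tpr, 0.9)
  expect_equal(m$f1, 90)
  # +100 ms and -100 ms errors -> RMSD 100 ms
  expect_equal(m$onset_bias_ms, 100)
  expect_true(is.na(m$offset_bias_ms)) # no offset TPs
})

test_that("a perfect detector scores TPR 1, F1 100, bias 0", {
  rec <- tiny_recording(81, duration = 25, n_bursts = 5)
  m <- evaluate_detection(rec$truth, rec$truth,
                          duration = length(rec$signal) / rec$fs)
  expect_equal(m$onset_tpr, 1)
  expect_equal(m$offset_tpr, 1)
  expect_equal(m$f1, 100)
  expect_equal(m$onset_bias_ms, 0)
  expect_equal(m$offset_bias_ms, 0)
})

test_that("onsets and offsets are scored by identical machinery", {
  truth <- cp_from_bursts(c(1, 3), c(2, 4))
  reg <- build_regions(truth, 6)
  # same displacement applied to onsets only vs offsets only
  d_on <- cp_from_bursts(c(1.05, 3.05), c(2, 4))
  d_off <- cp_from_bursts(c(1, 3), c(2.05, 4.05))
  m_on <- compute_metrics(classify_events(d_on, reg), truth)
  m_off <- compute_metrics(classify_events(d_off, reg), truth)
  expect_equal(m_on$onset_bias_ms, m_off$offset_bias_ms)
  expect_equal(m_on$onset_tpr, m_off$offset_tpr)
})
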