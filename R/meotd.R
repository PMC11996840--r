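#' Baseline noise statistics and first threshold
#'
#' The double-threshold detector assumes the first `Lb` samples of the
#' recording are activity-free. That prefix of the conditioned energy
#' series is framed with window `Ls` and hop `s`; the threshold is
#'
#'   `Th1 = mean(frame means) + j * mean(frame sds)`
#'
#' where the frame sds are population standard deviations and `j` is the
#' threshold scaling factor trading false alarms against detection
#' probability.
#'
#' @param energy Numeric conditioned energy series.
#' @param Lb Baseline length in samples (`>= Ls`).
#' @param Ls Frame length in samples.
#' @param s Frame hop in samples.
#' @param j Threshold scaling factor (dimensionless).
#' @return An object of class `baseline_model`: list with `frame_means`,
#'   `frame_sds`, `win_num`, `th1` and the parameters.
#' @examples
#' estimate_baseline(c(1, 1, 1, 3, 3, 3), Lb = 6, Ls = 3, s = 3, j = 2)$th1
#' @export
estimate_baseline <- function(energy, Lb, Ls = 128L, s = 64L, j = 5) {
  e <- as.numeric(energy)
  Lb <- as.integer(Lb); Ls <- as.integer(Ls); s <- as.integer(s)
  if (Ls < 1L || s < 1L) stop("'Ls' and 's' must be >= 1", call. = FALSE)
  if (Lb < Ls) stop("baseline length 'Lb' must be >= frame length 'Ls'",
                    call. = FALSE)
  if (Lb > length(e)) stop("'Lb' exceeds the series length", call. = FALSE)
  win_num <- (Lb - Ls) %/% s + 1L
  means <- sds <- numeric(win_num)
  for (i in seq_len(win_num)) {
    fr <- e[((i - 1L) * s + 1L):((i - 1L) * s + Ls)]
    m <- mean(fr)
    means[i] <- m
    sds[i] <- sqrt(mean((fr - m)^2))  # population sd
  }
  structure(list(frame_means = means, frame_sds = sds, win_num = win_num,
                 Lb = Lb, Ls = Ls, s = s, j = j,
                 th1 = mean(means) + j * mean(sds)),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> %d frames (Ls=%d, s=%d), j=%g, Th1=%.6g\n",
              x$win_num, x$Ls, x$s, x$j, x$th1))
  invisible(x)
}

# Per-sample length of the TRUE run starting at each position.
run_ahead <- function(b) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(length(b))
  for (i in which(r$values)) out[starts[i]:ends[i]] <- ends[i] - (starts[i]:ends[i]) + 1L
  out
}

#' Double-threshold scan over an energy series
#'
#' Scanning left to right, an onset is declared at the earliest sample
#' `E_n` whose next `Ton` samples are all strictly above `th1`; after an
#' onset, an offset is declared at the earliest later sample `E_m` whose
#' next `Toff` samples are all strictly below `th1` (ties at exactly `th1`
#' satisfy neither test). The scan resumes after `E_m + Toff`. A trailing
#' activity with no qualifying offset is closed at the final sample. `Ton`
#' and `Toff` encode the minimum contraction duration (about 100 ms) and
#' minimum switching time (25-30 ms) of muscle physiology.
#'
#' @param energy Numeric conditioned energy series.
#' @param th1 Amplitude threshold (energy units).
#' @param ton Onset persistence in samples (`>= 1`).
#' @param toff Offset persistence in samples (`>= 1`).
#' @param fs Sampling rate used to attach event times (Hz).
#' @return A [change_points] object (empty when nothing qualifies).
#' @export
double_threshold_scan <- function(energy, th1, ton, toff, fs = 1) {
  e <- as.numeric(energy)
  n <- length(e)
  ton <- as.integer(ton); toff <- as.integer(toff)
  if (ton < 1L || toff < 1L) stop("'ton' and 'toff' must be >= 1",
                                  call. = FALSE)
  above_run <- run_ahead(e > th1)
  below_run <- run_ahead(e < th1)
  on_idx <- integer(0); off_idx <- integer(0)
  i <- 1L
  while (i <= n) {
    cand <- which(above_run[i:n] >= ton)
    if (!length(cand)) break
    en <- i + cand[1L] - 1L
    if (en >= n) break  # an onset at the very last sample has no extent
    em <- n  # trailing unclosed activity closes at the last sample
    cand2 <- which(below_run[(en + 1L):n] >= toff)
    if (length(cand2)) em <- en + cand2[1L]
    on_idx <- c(on_idx, en); off_idx <- c(off_idx, em)
    i <- em + toff
  }
  if (!length(on_idx)) {
    return(change_points(character(), numeric(), index = integer()))
  }
  times <- as.vector(rbind((on_idx - 1) / fs, (off_idx - 1) / fs))
  change_points(rep(c("onset", "offset"), length(on_idx)), times,
                index = as.vector(rbind(on_idx, off_idx)))
}

#' Baseline double-threshold EMG activity detector (MEOTD)
#'
#' Full pipeline: multi-resolution energy [mteo] -> median conditioning
#' [median_smooth] -> baseline threshold [estimate_baseline] on the
#' activity-free prefix -> [double_threshold_scan]. Millisecond parameters
#' are converted to samples with [ms_to_samples] so they are independent of
#' the sampling rate.
#'
#' @param x An [emg_signal], an `emg_recording`, or a numeric vector (then
#'   `fs` is required).
#' @param k_max MTEO pooling scale. Default 15.
#' @param L Median window (odd samples). Default 15.
#' @param j Threshold scaling factor. Default 5.
#' @param ton_ms Onset persistence (ms). Default 100.
#' @param toff_ms Offset persistence (ms). Default 30.
#' @param baseline_ms Activity-free prefix used for noise statistics (ms).
#'   Default 1000.
#' @param frame Baseline frame length in samples. Default 128.
#' @param step Baseline frame hop in samples. Default 64.
#' @param rectified Use the full-wave rectified energy (the "a" variants).
#' @param fs Sampling rate when `x` is a bare vector.
#' @param scales Optional explicit MTEO scale set (see [mteo]).
#' @return An object of class `c("meotd", "emg_detection")` with elements
#'   `events` ([change_points]), `energy` (conditioned series), `baseline`
#'   (`baseline_model`), `params`, `fs`, `n` and `method`.
#' @examples
#' rec <- simulate_emg(duration = 12, n_bursts = 3, seed = 7)
#' fit <- meotd(rec)
#' fit$events
#' @export
meotd <- function(x, k_max = 15L, L = 15L, j = 5, ton_ms = 100,
                  toff_ms = 30, baseline_ms = 1000, frame = 128L,
                  step = 64L, rectified = FALSE, fs = NULL, scales = NULL) {
  if (inherits(x, "emg_recording")) x <- x$signal
  sig <- as_emg_signal(x, fs)
  if (ton_ms < toff_ms) {
    stop("'ton_ms' must be >= 'toff_ms' (contraction outlasts switching)",
         call. = FALSE)
  }
  e <- mteo(sig, k_max = k_max, rectified = rectified, scales = scales)
  e <- median_smooth(e, L)
  bl <- estimate_baseline(e, Lb = ms_to_samples(baseline_ms, sig$fs),
                          Ls = frame, s = step, j = j)
  ev <- double_threshold_scan(e, bl$th1,
                              ton = ms_to_samples(ton_ms, sig$fs),
                              toff = ms_to_samples(toff_ms, sig$fs),
                              fs = sig$fs)
  structure(list(events = ev, energy = e, baseline = bl,
                 params = list(k_max = k_max, L = L, j = j,
                               ton_ms = ton_ms, toff_ms = toff_ms,
                               baseline_ms = baseline_ms, frame = frame,
                               step = step, rectified = rectified),
                 fs = sig$fs, n = length(sig), method = "meotd"),
            class = c("meotd", "emg_detection"))
}
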