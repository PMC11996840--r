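#' Pure cosine test signal
#'
#' `x_n = A * cos(omega * n + phase)` for `n = 0, ..., n_samples - 1`.
#' Used as a closed-form oracle for the energy operators: the interior
#' lag-k energy of this signal is the constant `A^2 * sin(k * omega)^2`.
#'
#' @param amplitude Amplitude `A >= 0` (arbitrary units).
#' @param omega Angular frequency in radians per sample, `0 < omega < pi`.
#' @param phase Phase in radians.
#' @param n_samples Length of the signal, at least 3.
#' @param fs Sampling rate attached to the result (Hz); defaults to 1 so
#'   that `omega` is also radians per second.
#' @return An [emg_signal].
#' @examples
#' generate_sinusoid(1, pi / 2, n_samples = 4)$samples # 1 0 -1 0
#' @export
generate_sinusoid <- function(amplitude, omega, phase = 0, n_samples,
                              fs = 1) {
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("'amplitude' must be >= 0", call. = FALSE)
  }
  if (!is.finite(omega) || omega <= 0 || omega >= pi) {
    stop("'omega' must lie in (0, pi) radians/sample", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 3L) {
    stop("'n_samples' must be at least 3", call. = FALSE)
  }
  n <- seq_len(n_samples) - 1L
  emg_signal(amplitude * cos(omega * n + phase), fs = fs)
}

# Deterministic burst placement: durations in [dur_min, dur_max], first
# onset at lead_in, gaps >= min_gap, last offset <= duration - tail.
place_bursts <- function(n_bursts, duration, dur_range, min_gap, lead_in,
                         tail_s) {
  d <- stats::runif(n_bursts, dur_range[1], dur_range[2])
  occupied <- sum(d) + (n_bursts - 1) * min_gap + lead_in + tail_s
  slack <- duration - occupied
  if (slack < 0) {
    stop(sprintf(paste0("cannot place %d bursts of %.2g-%.2g s with %.2g s ",
                        "gaps in %.4g s"),
                 n_bursts, dur_range[1], dur_range[2], min_gap, duration),
         call. = FALSE)
  }
  # split the slack over the n_bursts - 1 gaps plus the tail
  cuts <- sort(stats::runif(n_bursts, 0, slack))
  extra <- diff(c(0, cuts))
  onset <- lead_in + cumsum(c(0, d[-n_bursts] + min_gap)) +
    cumsum(extra)
  data.frame(onset = onset, offset = onset + d)
}

#' Simulate a labelled synthetic surface-EMG recording
#'
#' Gaussian baseline noise everywhere, plus, inside each burst, zero-phase
#' band-pass-filtered Gaussian noise (a standard amplitude-modulated
#' band-limited surrogate for voluntary-contraction EMG) scaled to standard
#' deviation `baseline_sigma * 10^(snr_db / 20)` and shaped by a
#' trapezoidal envelope with linear ramps. The ramp start is the labelled
#' onset and the ramp end the labelled offset, giving an unambiguous ground
#' truth for timing-bias measurement. Identical seeds give bit-identical
#' recordings.
#'
#' @param fs Sampling rate (Hz). Default 1024.
#' @param duration Recording length (s). Default 120.
#' @param n_bursts Number of bursts when `bursts` is not given. Default 30.
#' @param burst_duration Length-2 range of burst durations (s),
#'   each at least 0.2 s.
#' @param snr_db Burst-to-baseline SNR in dB: burst sd is
#'   `baseline_sigma * 10^(snr_db / 20)`.
#' @param baseline_sigma Baseline noise sd (signal units). When 0 the
#'   baseline is exactly zero and the burst sd falls back to `burst_sigma`.
#' @param burst_sigma Optional explicit burst sd overriding the SNR rule.
#' @param band Length-2 band-pass corner frequencies (Hz), inside
#'   `(0, fs / 2)`. Default 20-450 Hz.
#' @param ramp_s Linear ramp duration at each burst edge (s). Default 0.05.
#' @param min_gap Minimum separation between bursts (s). Default 0.6, which
#'   keeps the +-300/200 ms evaluation intervals of adjacent bursts from
#'   overlapping.
#' @param lead_in Activity-free prefix before the first onset (s). Default
#'   2, long enough for baseline noise-statistics estimation.
#' @param bursts Optional data frame with columns `onset`, `offset`
#'   (seconds) fixing the burst times explicitly.
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @return An object of class `emg_recording`: list with elements `signal`
#'   ([emg_signal]), `truth` ([change_points]), `bursts`, `fs`, `snr_db`,
#'   `baseline_sigma`, `burst_sigma`, `band`, `ramp_s` and `seed`.
#' @examples
#' rec <- simulate_emg(duration = 10, n_bursts = 3, seed = 1)
#' rec$truth
#' @export
simulate_emg <- function(fs = 1024, duration = 120, n_bursts = 30,
                         burst_duration = c(0.5, 2), snr_db = 20,
                         baseline_sigma = 1, burst_sigma = NULL,
                         band = c(20, 450), ramp_s = 0.05, min_gap = 0.6,
                         lead_in = 2, bursts = NULL, seed = NULL) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    stop("'band' must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  if (baseline_sigma < 0) stop("'baseline_sigma' must be >= 0", call. = FALSE)
  if (is.null(burst_sigma)) {
    burst_sigma <- if (baseline_sigma > 0) {
      baseline_sigma * 10^(snr_db / 20)
    } else 1
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  if (is.null(bursts)) {
    bursts <- place_bursts(n_bursts, duration, burst_duration, min_gap,
                           lead_in, tail_s = 0.5)
  } else {
    bursts <- bursts[order(bursts$onset), , drop = FALSE]
    n_bursts <- nrow(bursts)
    dur <- bursts$offset - bursts$onset
    if (any(dur < 0.2)) stop("bursts must last at least 0.2 s", call. = FALSE)
    if (n_bursts > 1 &&
        any(bursts$onset[-1] - bursts$offset[-n_bursts] < min_gap)) {
      stop(sprintf("bursts must be separated by at least %.2g s", min_gap),
           call. = FALSE)
    }
    if (bursts$onset[1] < 0 || bursts$offset[n_bursts] > duration) {
      stop("bursts must lie inside the recording", call. = FALSE)
    }
  }
  n <- as.integer(round(duration * fs))
  x <- if (baseline_sigma > 0) stats::rnorm(n, 0, baseline_sigma) else numeric(n)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  pad <- as.integer(fs)  # discard filter transients at the segment edges
  ramp_n <- max(1L, as.integer(round(ramp_s * fs)))
  for (b in seq_len(nrow(bursts))) {
    # burst samples lie strictly inside [onset, offset]
    i0 <- as.integer(ceiling(bursts$onset[b] * fs)) + 1L
    i1 <- min(as.integer(floor(bursts$offset[b] * fs)) + 1L, n)
    len <- i1 - i0 + 1L
    raw <- stats::rnorm(len + 2L * pad)
    bb <- signal::filtfilt(bf, raw)[pad + seq_len(len)]
    bb <- bb / stats::sd(bb) * burst_sigma
    env <- rep(1, len)
    r <- min(ramp_n, len %/% 2L)
    if (r > 0L) {
      env[seq_len(r)] <- seq(0, 1, length.out = r + 1L)[-1L]
      env[len - seq_len(r) + 1L] <- seq(0, 1, length.out = r + 1L)[-1L]
    }
    x[i0:i1] <- x[i0:i1] + bb * env
  }
  truth <- cp_from_bursts(bursts$onset, bursts$offset, fs = fs)
  structure(list(signal = emg_signal(x, fs), truth = truth, bursts = bursts,
                 fs = fs, snr_db = snr_db, baseline_sigma = baseline_sigma,
                 burst_sigma = burst_sigma, band = band, ramp_s = ramp_s,
                 seed = seed),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(paste0("<emg_recording> %.4g s at %g Hz, %d bursts, ",
                     "snr %.3g dB, baseline sd %.3g\n"),
              length(x$signal) / x$fs, x$fs, nrow(x$bursts), x$snr_db,
              x$baseline_sigma))
  invisible(x)
}
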