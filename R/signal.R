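#' Uniformly sampled single-channel EMG signal
#'
#' Light container pairing an amplitude vector with its sampling rate.
#' All detectors and the synthetic generator consume and produce this class.
#'
#' @param samples Numeric vector of amplitudes (signal units).
#' @param fs Sampling rate in Hz (> 0).
#'
#' @return An object of class `emg_signal`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' x <- emg_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 256)), fs = 256)
#' x
#' @export
emg_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 3L) {
    stop("an EMG signal needs at least 3 samples", call. = FALSE)
  }
  if (anyNA(samples)) stop("signal contains NA samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "emg_signal")
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf("<emg_signal> %d samples at %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.emg_signal <- function(x) length(x$samples)

# Accept either an emg_signal or a bare numeric vector plus fs.
as_emg_signal <- function(x, fs = NULL) {
  if (inherits(x, "emg_signal")) return(x)
  if (is.null(fs)) stop("'fs' is required when 'x' is a bare vector",
                        call. = FALSE)
  emg_signal(x, fs)
}

#' Convert a duration in milliseconds to a whole number of samples
#'
#' The single place where millisecond parameters (minimum activation
#' duration, baseline length, ...) are turned into sample counts, so every
#' stage rounds identically: `round(ms * fs / 1000)`.
#'
#' @param ms Duration in milliseconds.
#' @param fs Sampling rate in Hz.
#' @return Integer number of samples.
#' @examples
#' ms_to_samples(30, 1024) # 31
#' @export
ms_to_samples <- function(ms, fs) {
  if (any(!is.finite(ms)) || any(ms < 0)) {
    stop("'ms' must be finite and non-negative", call. = FALSE)
  }
  as.integer(round(ms * fs / 1000))
}
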