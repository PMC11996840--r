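#' Lag-k Teager-Kaiser energy operator
#'
#' Computes the instantaneous frequency-weighted "energy"
#' `psi_k(x_n) = x_n^2 - x_{n+k} * x_{n-k}`. With `k = 1` this is the
#' classic three-sample Teager-Kaiser operator; larger lags emphasize lower
#' frequencies. For a pure sinusoid `A*cos(w*n)` the interior output is the
#' constant `A^2 * sin(k*w)^2`.
#'
#' Boundary convention: the `k` samples at each end, where `x_{n+k}` or
#' `x_{n-k}` would fall outside the recording, are set to 0 rather than
#' computed from fabricated samples.
#'
#' @param x An [emg_signal] or numeric vector.
#' @param k Positive integer lag, at most `(length(x) - 1) / 2`.
#' @param rectified If `TRUE`, return the full-wave rectified (absolute)
#'   energy.
#' @return Numeric vector of energies, index-aligned with `x`, with
#'   attributes `scale` (the lag) and `rectified`.
#' @examples
#' kteo(c(1, 2, 3, 4, 5), k = 1) # 0 1 1 1 0
#' @export
kteo <- function(x, k = 1L, rectified = FALSE) {
  v <- if (inherits(x, "emg_signal")) x$samples else as.numeric(x)
  n <- length(v)
  if (n < 3L) stop("signal must have at least 3 samples", call. = FALSE)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > (n - 1L) %/% 2L) {
    stop(sprintf("'k' must be an integer in [1, %d] for a length-%d signal",
                 (n - 1L) %/% 2L, n), call. = FALSE)
  }
  p <- numeric(n)
  idx <- (k + 1L):(n - k)
  p[idx] <- v[idx]^2 - v[idx + k] * v[idx - k]
  if (rectified) p <- abs(p)
  structure(p, scale = k, rectified = rectified)
}

#' Multi-resolution Teager energy operator (MTEO)
#'
#' Pointwise maximum of the lag-k energies [kteo] over scales
#' `k = 1, ..., k_max`, pooling energy across frequency resolutions.
#' Near the boundaries each sample pools only the scales that are defined
#' there (no zero-padding enters the maximum); the first and last sample,
#' where no scale is defined, are 0.
#'
#' @inheritParams kteo
#' @param k_max Largest scale to pool, at most `(length(x) - 1) / 2`.
#' @param scales Optional explicit integer scale set overriding
#'   `1:k_max` (e.g. odd scales only).
#' @return Numeric vector of pooled energies aligned with `x`, with
#'   attributes `k_max` and `rectified`.
#' @examples
#' mteo(c(0, 0, 3, 0, 0), k_max = 2)[3] # 9
#' @export
mteo <- function(x, k_max = 15L, rectified = FALSE, scales = NULL) {
  v <- if (inherits(x, "emg_signal")) x$samples else as.numeric(x)
  n <- length(v)
  if (is.null(scales)) {
    k_max <- as.integer(k_max)
    if (length(k_max) != 1L || is.na(k_max) || k_max < 1L ||
        k_max > (n - 1L) %/% 2L) {
      stop(sprintf("'k_max' must be an integer in [1, %d]", (n - 1L) %/% 2L),
           call. = FALSE)
    }
    scales <- seq_len(k_max)
  } else {
    scales <- sort(unique(as.integer(scales)))
    if (any(scales < 1L) || any(scales > (n - 1L) %/% 2L)) {
      stop("'scales' out of range for this signal length", call. = FALSE)
    }
    k_max <- max(scales)
  }
  p <- rep(-Inf, n)
  for (k in scales) {
    idx <- (k + 1L):(n - k)
    val <- v[idx]^2 - v[idx + k] * v[idx - k]
    if (rectified) val <- abs(val)
    p[idx] <- pmax(p[idx], val)
  }
  p[!is.finite(p)] <- 0
  structure(p, k_max = k_max, rectified = rectified)
}
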