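#' Canonical fixed neuron weights of the network-style detector
#'
#' The energy "convolution" channel of the network detector is a fixed
#' neuron `C_k(n) = W1*(w11*x_{n+k})^2 + W2*(w22*x_n)^2 +
#' W3*(w33*x_{n-k})^2 + W4*(w14*x_{n+k} + w34*x_{n-k})^2`. With the
#' canonical values `W1 = W2 = W3 = 1, W4 = -1, w11 = w14 = 2, w22 = 1,
#' w33 = w34 = 1/4` the squared terms cancel algebraically
#' (`4 - 4 = 0`, `1/16 - 1/16 = 0`, cross term `-2*2*(1/4) = -1`) and the
#' channel is identically the lag-k energy operator [kteo]. The layer is
#' fixed: no other weights are accepted.
#'
#' @return Named list of the canonical weights.
#' @export
network_weights <- function() {
  list(W1 = 1, W2 = 1, W3 = 1, W4 = -1,
       w11 = 2, w14 = 2, w22 = 1, w33 = 0.25, w34 = 0.25)
}

#' Fixed-weight energy convolution channel
#'
#' Evaluates the neuron expression literally (squared activation on each
#' weighted tap); by construction it equals `kteo(x, k)` to machine
#' precision. Boundary samples within `k` of either end are 0, as in
#' [kteo].
#'
#' @inheritParams kteo
#' @param weights Must be the canonical [network_weights]; anything else is
#'   rejected because the layer is fixed, not trainable.
#' @return Numeric energy vector aligned with `x`.
#' @export
conv_energy_layer <- function(x, k = 1L, weights = network_weights()) {
  canon <- network_weights()
  if (!isTRUE(all.equal(weights[order(names(weights))],
                        canon[order(names(canon))], tolerance = 0))) {
    stop("the energy convolution layer is fixed; weights must equal network_weights()",
         call. = FALSE)
  }
  v <- if (inherits(x, "emg_signal")) x$samples else as.numeric(x)
  n <- length(v)
  k <- as.integer(k)
  if (k < 1L || k > (n - 1L) %/% 2L) {
    stop("'k' out of range for this signal length", call. = FALSE)
  }
  p <- numeric(n)
  idx <- (k + 1L):(n - k)
  xp <- v[idx + k]; x0 <- v[idx]; xm <- v[idx - k]
  p[idx] <- weights$W1 * (weights$w11 * xp)^2 +
    weights$W2 * (weights$w22 * x0)^2 +
    weights$W3 * (weights$w33 * xm)^2 +
    weights$W4 * (weights$w14 * xp + weights$w34 * xm)^2
  p
}

#' Min-max sampling layer
#'
#' Normalizes a pooled energy series to `[0, 1]`. The default reference is
#' the series-wide minimum and maximum, so baseline energy (a small
#' fraction of the burst maximum) maps near 0 and burst energy near 1.
#' `window` switches to a causal variant for streaming use: extremes over
#' the trailing half-open window `(i - window, i]`, truncated to the
#' available prefix for early samples. Wherever max equals min the output
#' is 0.
#'
#' @param energy Numeric pooled (and conditioned) energy series.
#' @param window `NULL` for series-wide normalization (default), or a
#'   positive integer trailing-window length in samples (the network
#'   detector uses `2 * k_max`).
#' @return Numeric vector in `[0, 1]`, same length as `energy`.
#' @export
minmax_normalize <- function(energy, window = NULL) {
  e <- as.numeric(energy)
  n <- length(e)
  if (is.null(window)) {
    mn <- min(e); mx <- max(e)
    if (mx > mn) return((e - mn) / (mx - mn))
    return(numeric(n))
  }
  window <- as.integer(window)
  if (window < 1L) stop("'window' must be >= 1", call. = FALSE)
  y <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    w <- e[lo:i]
    mn <- min(w); mx <- max(w)
    y[i] <- if (mx > mn) (e[i] - mn) / (mx - mn) else 0
  }
  y
}

#' Sigmoid hard-limiter classifier
#'
#' Maps the normalized series through the logistic sigmoid
#' `1 / (1 + exp(-y))` and thresholds at `T`: a sample is active when
#' `sigmoid(y) >= T` (ties activate). Because `y` lies in `[0, 1]`, the
#' sigmoid output lies in `[0.5, 0.7311]`, which is why the useful range of
#' `T` sits just above 0.5.
#'
#' @param y Numeric series (typically in `[0, 1]`).
#' @param threshold Classifier threshold `T` in (0, 1). Default 0.506.
#' @return Integer 0/1 mask of the same length.
#' @examples
#' classify_mask(c(0, 1), 0.506) # 0 1
#' @export
classify_mask <- function(y, threshold = 0.506) {
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  }
  as.integer(1 / (1 + exp(-as.numeric(y))) >= threshold)
}

#' Remove physiologically implausible short activations
#'
#' Every maximal run of ones shorter than `min_len` samples is zeroed;
#' nothing else changes. Encodes the ~30 ms minimum muscle-activation
#' duration. Gaps between runs are never merged.
#'
#' @param mask Integer/logical 0/1 vector.
#' @param min_len Minimum run length in samples.
#' @return Integer 0/1 vector.
#' @export
prune_short_runs <- function(mask, min_len) {
  m <- as.integer(mask != 0)
  min_len <- as.integer(min_len)
  if (min_len <= 1L || !any(m == 1L)) return(m)
  r <- rle(m)
  r$values[r$values == 1L & r$lengths < min_len] <- 0L
  inverse.rle(r)
}

#' Forward pass of the network-style detector
#'
#' Channels `C_1 .. C_{k_max}` via [conv_energy_layer] (optionally
#' rectified), pointwise max pooling across channels (each boundary sample
#' pools only the channels defined there), median conditioning of the
#' pooled series, then the [minmax_normalize] sampling layer.
#'
#' @inheritParams meonnd
#' @return Numeric series in `[0, 1]` aligned with the signal.
#' @export
meonnd_forward <- function(x, k_max = 15L, L = 15L, rectified = FALSE,
                           normalization = c("global", "causal"),
                           fs = NULL, scales = NULL) {
  normalization <- match.arg(normalization)
  sig <- as_emg_signal(x, fs)
  if (length(sig) <= 2L * max(if (is.null(scales)) k_max else scales)) {
    stop("signal too short for the requested scale set", call. = FALSE)
  }
  ks <- if (is.null(scales)) seq_len(as.integer(k_max)) else
    sort(unique(as.integer(scales)))
  n <- length(sig)
  p <- rep(-Inf, n)
  for (k in ks) {
    ck <- conv_energy_layer(sig, k)
    if (rectified) ck <- abs(ck)
    idx <- (k + 1L):(n - k)
    p[idx] <- pmax(p[idx], ck[idx])
  }
  p[!is.finite(p)] <- 0
  p <- median_smooth(p, L)
  win <- if (normalization == "causal") 2L * max(ks) else NULL
  minmax_normalize(p, window = win)
}

#' Fixed-weight network-style EMG activity detector (MEONND)
#'
#' Pipeline: [meonnd_forward] -> [classify_mask] -> [prune_short_runs] ->
#' [mask_to_changepoints]. Needs no baseline prior: the energy layers are
#' degree-2 homogeneous and the sampling layer normalizes scale, so the
#' output is invariant to global amplitude scaling of the signal.
#'
#' @param x An [emg_signal], an `emg_recording`, or a numeric vector (then
#'   `fs` is required).
#' @param k_max Number of energy channels (scales). Default 15.
#' @param L Median window (odd samples). Default 15.
#' @param threshold Classifier threshold `T`. Default 0.506.
#' @param min_on_ms Minimum activation duration (ms). Default 30.
#' @param rectified Use rectified channel energies.
#' @param normalization `"global"` (series-wide min-max, default) or
#'   `"causal"` (trailing `2 * k_max`-sample window).
#' @param fs Sampling rate when `x` is a bare vector.
#' @param scales Optional explicit channel scale set.
#' @return An object of class `c("meonnd", "emg_detection")` with elements
#'   `events`, `activation` (the normalized series), `mask`, `params`,
#'   `fs`, `n` and `method`.
#' @examples
#' rec <- simulate_emg(duration = 12, n_bursts = 3, seed = 7)
#' fit <- meonnd(rec)
#' fit$events
#' @export
meonnd <- function(x, k_max = 15L, L = 15L, threshold = 0.506,
                   min_on_ms = 30, rectified = FALSE,
                   normalization = c("global", "causal"), fs = NULL,
                   scales = NULL) {
  normalization <- match.arg(normalization)
  if (inherits(x, "emg_recording")) x <- x$signal
  sig <- as_emg_signal(x, fs)
  y <- meonnd_forward(sig, k_max = k_max, L = L, rectified = rectified,
                      normalization = normalization, scales = scales)
  mask <- classify_mask(y, threshold)
  mask <- prune_short_runs(mask, ms_to_samples(min_on_ms, sig$fs))
  ev <- mask_to_changepoints(mask, sig$fs)
  structure(list(events = ev, activation = y, mask = mask,
                 params = list(k_max = k_max, L = L, threshold = threshold,
                               min_on_ms = min_on_ms, rectified = rectified,
                               normalization = normalization),
                 fs = sig$fs, n = length(sig), method = "meonnd"),
            class = c("meonnd", "emg_detection"))
}
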