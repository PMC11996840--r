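#' Median conditioning of an energy series
#'
#' Order-statistics filtering that suppresses the isolated spikes energy
#' operators produce on noisy signals (where a mean filter would smear the
#' spike instead of removing it).
#'
#' Two variants are provided. `"sliding"` (default) is a hop-1 centered
#' median of window `L`, keeping the output sample-aligned for per-sample
#' change-point detection; near the edges the window shrinks symmetrically
#' to the available samples (always an odd count), so no padding values are
#' invented. `"frame"` computes one median per non-overlapping frame of `L`
#' samples and holds it for the frame (coinciding with the sliding variant
#' at frame centers); a final short frame keeps its own median.
#'
#' @param energy Numeric energy series (e.g. from [mteo]).
#' @param L Odd window length, `3 <= L <= length(energy)`.
#' @param variant `"sliding"` or `"frame"`.
#' @return Numeric vector of the same length as `energy`.
#' @examples
#' median_smooth(c(1, 100, 2), L = 3) # spike removed at the center
#' @export
median_smooth <- function(energy, L, variant = c("sliding", "frame")) {
  variant <- match.arg(variant)
  e <- as.numeric(energy)
  n <- length(e)
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 3L || L %% 2L == 0L) {
    stop("'L' must be an odd integer >= 3", call. = FALSE)
  }
  if (L > n) stop("'L' exceeds the series length", call. = FALSE)
  if (variant == "sliding") {
    out <- as.numeric(stats::runmed(e, L, endrule = "keep"))
    # shrinking symmetric windows at the edges (always an odd count)
    h <- (L - 1L) %/% 2L
    for (i in seq_len(min(h, n))) {
      hh <- min(i - 1L, n - i)
      out[i] <- stats::median(e[(i - hh):(i + hh)])
      j <- n - i + 1L
      hh <- min(j - 1L, n - j)
      out[j] <- stats::median(e[(j - hh):(j + hh)])
    }
    out
  } else {
    out <- numeric(n)
    starts <- seq(1L, n, by = L)
    for (s in starts) {
      idx <- s:min(s + L - 1L, n)
      out[idx] <- stats::median(e[idx])
    }
    out
  }
}
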