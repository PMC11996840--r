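#' Alternating onset/offset change-point set
#'
#' Ordered set of muscle-activity change-points. Events must strictly
#' alternate starting with an onset, with strictly increasing times; each
#' onset precedes its paired offset. Used both for detector output and for
#' synthetic ground truth.
#'
#' @param event Character vector, each element `"onset"` or `"offset"`.
#' @param time_s Numeric vector of event times in seconds.
#' @param index Optional integer vector of 1-based sample indices; derived
#'   from `time_s` when `fs` is given.
#' @param fs Optional sampling rate used to derive `index`.
#'
#' @return A data frame of class `change_points` with columns `event`,
#'   `time_s` and (when available) `index`.
#' @examples
#' change_points(c("onset", "offset"), c(1.2, 2.0))
#' @export
change_points <- function(event = character(), time_s = numeric(),
                          index = NULL, fs = NULL) {
  event <- as.character(event)
  time_s <- as.numeric(time_s)
  if (length(event) != length(time_s)) {
    stop("'event' and 'time_s' lengths differ", call. = FALSE)
  }
  if (!all(event %in% c("onset", "offset"))) {
    stop("events must be 'onset' or 'offset'", call. = FALSE)
  }
  n <- length(event)
  if (n > 0L) {
    expected <- rep(c("onset", "offset"), length.out = n)
    if (!identical(event, expected)) {
      stop("events must strictly alternate starting with an onset",
           call. = FALSE)
    }
    if (any(diff(time_s) <= 0)) {
      stop("event times must be strictly increasing", call. = FALSE)
    }
  }
  if (is.null(index) && !is.null(fs)) index <- as.integer(round(time_s * fs)) + 1L
  df <- data.frame(event = event, time_s = time_s,
                   stringsAsFactors = FALSE)
  if (!is.null(index)) df$index <- as.integer(index)
  class(df) <- c("change_points", "data.frame")
  df
}

#' Build a change-point set from paired onset/offset time vectors
#'
#' @param onset,offset Numeric vectors of equal length (seconds); each
#'   onset must precede its offset and bursts must not overlap.
#' @param fs Optional sampling rate used to attach sample indices.
#' @return A [change_points] object.
#' @export
cp_from_bursts <- function(onset, offset, fs = NULL) {
  if (length(onset) != length(offset)) {
    stop("'onset' and 'offset' lengths differ", call. = FALSE)
  }
  o <- order(onset)
  onset <- onset[o]; offset <- offset[o]
  times <- as.vector(rbind(onset, offset))
  change_points(rep(c("onset", "offset"), times = length(onset)), times,
                fs = fs)
}

#' @export
print.change_points <- function(x, ...) {
  cat(sprintf("<change_points> %d events (%d bursts)\n",
              nrow(x), sum(x$event == "onset")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# Onset/offset extraction helpers used throughout.
cp_onsets <- function(cp) cp$time_s[cp$event == "onset"]
cp_offsets <- function(cp) cp$time_s[cp$event == "offset"]

#' Extract change-points from a binary activity mask
#'
#' Onsets are placed at the first sample of each run of ones; offsets at the
#' first zero sample after the run (a run reaching the end of the mask is
#' closed at the final sample, preserving alternation).
#'
#' @param mask Integer/logical vector of per-sample activity (0/1).
#' @param fs Sampling rate (Hz); times are `(index - 1) / fs`.
#' @return A [change_points] object with sample indices attached.
#' @export
mask_to_changepoints <- function(mask, fs) {
  mask <- as.integer(mask != 0)
  n <- length(mask)
  if (n == 0L || !any(mask == 1L)) return(change_points(fs = fs))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_idx <- starts[r$values == 1L]
  off_idx <- pmin(ends[r$values == 1L] + 1L, n)
  times <- as.vector(rbind((on_idx - 1) / fs, (off_idx - 1) / fs))
  idx <- as.vector(rbind(on_idx, off_idx))
  change_points(rep(c("onset", "offset"), length(on_idx)), times, index = idx)
}
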