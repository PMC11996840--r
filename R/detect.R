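#' Detect muscle-activity change-points in an EMG signal
#'
#' Front end dispatching to the two monitors: [meotd] (baseline
#' double-threshold) or [meonnd] (fixed-weight network-style). Additional
#' arguments are passed to the chosen detector.
#'
#' @param x An [emg_signal], `emg_recording`, or numeric vector.
#' @param method `"meotd"` or `"meonnd"`.
#' @param ... Passed to the detector.
#' @return An `emg_detection` object.
#' @examples
#' rec <- simulate_emg(duration = 12, n_bursts = 3, seed = 7)
#' detect_activity(rec, "meonnd")
#' @export
detect_activity <- function(x, method = c("meotd", "meonnd"), ...) {
  method <- match.arg(method)
  switch(method, meotd = meotd(x, ...), meonnd = meonnd(x, ...))
}

#' @export
print.emg_detection <- function(x, ...) {
  nb <- sum(x$events$event == "onset")
  cat(sprintf("<%s detection> %d bursts in %.4g s at %g Hz\n",
              toupper(x$method), nb, x$n / x$fs, x$fs))
  pp <- x$params
  cat("parameters:",
      paste(names(pp), vapply(pp, function(v) paste(format(v), collapse = ","),
                              ""), sep = "=", collapse = " "), "\n")
  if (x$method == "meotd") cat(sprintf("Th1 = %.6g\n", x$baseline$th1))
  invisible(x)
}

#' @export
summary.emg_detection <- function(object, ...) {
  ev <- object$events
  on <- cp_onsets(ev); off <- cp_offsets(ev)
  out <- list(method = object$method, n_bursts = length(on),
              durations_s = off - on, onsets_s = on,
              total_active_s = sum(off - on),
              recording_s = object$n / object$fs)
  class(out) <- "summary.emg_detection"
  out
}

#' @export
print.summary.emg_detection <- function(x, ...) {
  cat(sprintf("%s: %d bursts, %.3g of %.4g s active\n", toupper(x$method),
              x$n_bursts, x$total_active_s, x$recording_s))
  if (x$n_bursts) {
    cat("burst durations (s):\n")
    print(summary(x$durations_s))
  }
  invisible(x)
}

#' Plot a detection over its energy/activation trace
#'
#' Draws the conditioned energy (MEOTD, with the threshold line) or the
#' normalized activation (MEONND, with the sigmoid cut) and shades the
#' detected activity intervals.
#'
#' @param x An `emg_detection` object.
#' @param ... Passed to [graphics::plot].
#' @export
plot.emg_detection <- function(x, ...) {
  t <- (seq_len(x$n) - 1) / x$fs
  trace <- if (x$method == "meotd") as.numeric(x$energy) else x$activation
  ylab <- if (x$method == "meotd") "conditioned energy" else "activation"
  graphics::plot(t, trace, type = "l", xlab = "time (s)", ylab = ylab, ...)
  on <- cp_onsets(x$events); off <- cp_offsets(x$events)
  if (length(on)) {
    graphics::rect(on, graphics::par("usr")[3], off, graphics::par("usr")[4],
                   col = grDevices::adjustcolor("tomato", 0.2), border = NA)
  }
  if (x$method == "meotd") {
    graphics::abline(h = x$baseline$th1, lty = 2)
  } else {
    # activation level where sigmoid(y) crosses T
    tcut <- log(x$params$threshold / (1 - x$params$threshold))
    graphics::abline(h = tcut, lty = 2)
  }
  invisible(x)
}
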