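#' Read an EMG signal from CSV
#'
#' Accepts either a two-column file with header `time_s,emg` (the sampling
#' rate is inferred from the timestamps, which must be uniform to within
#' half a sample period) or a single `emg` column plus an explicit `fs`.
#'
#' @param path CSV path (comma-separated, UTF-8, header required).
#' @param fs Sampling rate (Hz); required for single-column files,
#'   cross-checked when timestamps are present.
#' @return An [emg_signal].
#' @export
read_emg_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"emg" %in% names(df)) {
    stop(sprintf("%s: missing required column 'emg'", path), call. = FALSE)
  }
  if ("time_s" %in% names(df)) {
    t <- df$time_s
    if (length(t) < 3L) stop(sprintf("%s: need at least 3 rows", path),
                             call. = FALSE)
    dt <- diff(t)
    if (any(dt <= 0)) {
      stop(sprintf("%s: timestamps not increasing at line %d", path,
                   which(dt <= 0)[1L] + 2L), call. = FALSE)
    }
    period <- stats::median(dt)
    if (max(abs(dt - period)) >= period / 2) {
      stop(sprintf("%s: non-uniform sampling near line %d", path,
                   which.max(abs(dt - period)) + 2L), call. = FALSE)
    }
    fs_file <- 1 / period
    if (!is.null(fs)) {
      # an explicit rate wins over the (precision-limited) timestamps,
      # provided they agree
      if (abs(fs_file - fs) > 0.01 * fs) {
        stop(sprintf("%s: timestamps imply fs = %.6g, not %.6g", path,
                     fs_file, fs), call. = FALSE)
      }
    } else {
      fs <- fs_file
    }
  } else if (is.null(fs)) {
    stop(sprintf("%s: no 'time_s' column, so 'fs' must be given", path),
         call. = FALSE)
  }
  emg_signal(df$emg, fs)
}

#' Write an EMG signal to CSV
#'
#' Two columns `time_s` (6 decimals) and `emg`; round-trips through
#' [read_emg_csv].
#'
#' @param x An [emg_signal].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(x, path) {
  stopifnot(inherits(x, "emg_signal"))
  t <- (seq_along(x$samples) - 1) / x$fs
  utils::write.csv(data.frame(time_s = sprintf("%.6f", t), emg = x$samples),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write change-point event files
#'
#' CSV with columns `event` (onset/offset) and `time_s`; an optional
#' `index` column carries 1-based sample indices. Alternation and ordering
#' are validated on read; events are written in time order.
#'
#' @param path CSV path.
#' @return [read_events]: a [change_points] object.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("event", "time_s") %in% names(df))) {
    stop(sprintf("%s: need columns 'event' and 'time_s'", path),
         call. = FALSE)
  }
  change_points(df$event, df$time_s,
                index = if ("index" %in% names(df)) df$index else NULL)
}

#' @rdname read_events
#' @param cp A [change_points] object.
#' @export
write_events <- function(cp, path) {
  stopifnot(inherits(cp, "change_points"))
  df <- as.data.frame(cp)
  df$time_s <- sprintf("%.6f", df$time_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a metrics report to JSON
#'
#' Flat JSON object with the five metrics plus the pooled confusion
#' counts; `NA` metrics are written as `null`.
#'
#' @param metrics An `emg_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "emg_metrics"))
  obj <- list(onset_tpr = metrics$onset_tpr,
              offset_tpr = metrics$offset_tpr,
              f1 = metrics$f1,
              onset_bias_ms = metrics$onset_bias_ms,
              offset_bias_ms = metrics$offset_bias_ms,
              counts = as.list(metrics$counts["pooled", ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
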