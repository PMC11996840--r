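#' Partition a recording into scoring regions around the true change-points
#'
#' Each true onset/offset gets a valid-detection segment spanning
#' `pre_ms` before to `post_ms` after the event (defaults 300/200 ms,
#' reflecting electromechanical delay and perceptible control latency).
#' The gap between a burst's onset segment and its offset segment is the
#' activity region; everything else is baseline. Regions tile `[0,
#' duration]` without overlap. Within a short burst the two segments may
#' abut (empty activity); they are then truncated at their midpoint.
#' Overlapping segments of *different* bursts are refused, since the
#' scoring rules are undefined there.
#'
#' @param truth A [change_points] ground-truth set.
#' @param duration Recording length in seconds.
#' @param pre_ms Segment extent before the event (ms). Default 300.
#' @param post_ms Segment extent after the event (ms). Default 200.
#' @return Data frame of class `region_partition`: columns `kind`
#'   (`baseline`/`onset_segment`/`activity`/`offset_segment`), `start`,
#'   `end` (s), `event_time` (s, `NA` for untargeted regions) and
#'   `event_type`.
#' @export
build_regions <- function(truth, duration, pre_ms = 300, post_ms = 200) {
  pre <- pre_ms / 1000; post <- post_ms / 1000
  on <- cp_onsets(truth); off <- cp_offsets(truth)
  nb <- length(on)
  rows <- list()
  add <- function(kind, start, end, etime = NA_real_,
                  etype = NA_character_) {
    if (end > start) {
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, start = start, end = end, event_time = etime,
        event_type = etype, stringsAsFactors = FALSE)
    }
  }
  cursor <- 0
  for (b in seq_len(nb)) {
    s_on <- max(0, on[b] - pre); e_on <- min(duration, on[b] + post)
    s_off <- max(0, off[b] - pre); e_off <- min(duration, off[b] + post)
    if (e_on > s_off) {
      # short burst: segments abut at the midpoint, empty activity
      mid <- (e_on + s_off) / 2
      e_on <- mid; s_off <- mid
    }
    if (s_on < cursor) {
      stop("valid detection intervals of consecutive bursts overlap; ",
           "scoring is undefined for such truth sets", call. = FALSE)
    }
    add("baseline", cursor, s_on)
    add("onset_segment", s_on, e_on, on[b], "onset")
    add("activity", e_on, s_off)
    add("offset_segment", s_off, e_off, off[b], "offset")
    cursor <- e_off
  }
  add("baseline", cursor, duration)
  if (!length(rows)) {
    out <- data.frame(kind = "baseline", start = 0, end = duration,
                      event_time = NA_real_, event_type = NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  class(out) <- c("region_partition", "data.frame")
  out
}

#' Region-classify detected events into the revised confusion matrix
#'
#' Scoring rules per region:
#' * onset segment: exactly one detected onset -> TP (the pair is kept for
#'   bias); no event -> FN; anything else (multiple events, or an offset)
#'   -> one FP and no TP.
#' * offset segment: symmetric.
#' * baseline / activity region: no events -> one TN for the region;
#'   otherwise one FP per detected event.
#'
#' Detected events outside `[0, duration]` are dropped with a warning.
#' Counts are split by event type (onset segments and onset-typed FPs feed
#' the onset column) and pooled.
#'
#' @param detected A [change_points] set from a detector.
#' @param regions A `region_partition` from [build_regions].
#' @return List of class `confusion_counts`: `counts` (3 x 4 matrix:
#'   onset/offset/pooled x TP/TN/FP/FN) and `pairs` (data frame of matched
#'   true/detected times per TP, with the event type).
#' @export
classify_events <- function(detected, regions) {
  duration <- max(regions$end)
  tm <- detected$time_s
  ty <- detected$event
  out_of_span <- tm < 0 | tm > duration
  if (any(out_of_span)) {
    warning(sprintf("%d detected event(s) outside the recording span dropped",
                    sum(out_of_span)))
    tm <- tm[!out_of_span]; ty <- ty[!out_of_span]
  }
  counts <- matrix(0L, nrow = 3, ncol = 4,
                   dimnames = list(c("onset", "offset", "pooled"),
                                   c("TP", "TN", "FP", "FN")))
  pairs <- list()
  seg <- regions$kind %in% c("onset_segment", "offset_segment")
  assigned <- rep(NA_integer_, length(tm))
  # segments are closed intervals and take priority over the open regions
  for (r in which(seg)) {
    hit <- which(is.na(assigned) & tm >= regions$start[r] &
                   tm <= regions$end[r])
    assigned[hit] <- r
  }
  for (r in which(!seg)) {
    hit <- which(is.na(assigned) & tm >= regions$start[r] &
                   tm < regions$end[r])
    assigned[hit] <- r
  }
  # any event at the exact end of the recording joins the last region
  assigned[is.na(assigned)] <- nrow(regions)
  bump <- function(type, what, by = 1L) {
    if (!is.na(type)) counts[type, what] <<- counts[type, what] + by
    counts["pooled", what] <<- counts["pooled", what] + by
  }
  for (r in seq_len(nrow(regions))) {
    here <- which(assigned == r)
    kind <- regions$kind[r]
    if (kind %in% c("baseline", "activity")) {
      if (!length(here)) {
        bump(NA, "TN")
      } else {
        for (i in here) bump(ty[i], "FP")
      }
    } else {
      etype <- regions$event_type[r]
      if (!length(here)) {
        bump(etype, "FN")
      } else if (length(here) == 1L && ty[here] == etype) {
        bump(etype, "TP")
        pairs[[length(pairs) + 1L]] <- data.frame(
          event = etype, true_s = regions$event_time[r],
          detected_s = tm[here], stringsAsFactors = FALSE)
      } else {
        bump(etype, "FP")
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(event = character(), true_s = numeric(),
               detected_s = numeric(), stringsAsFactors = FALSE)
  structure(list(counts = counts, pairs = pairs,
                 n_detected = c(onset = sum(ty == "onset"),
                                offset = sum(ty == "offset"))),
            class = "confusion_counts")
}

#' Detection metrics from region-classified counts
#'
#' True-positive rate per event type (`TP / N_true`), pooled F1 on the
#' 0-100 scale (`2 TP / (2 TP + FN + FP) * 100`), and onset/offset bias as
#' the root-mean-square deviation (ms) between matched detected and true
#' times. TPR is `NA` when there are no true events of a type; bias is
#' `NA` when a type has no true positives.
#'
#' @param classification A `confusion_counts` from [classify_events].
#' @param truth The ground-truth [change_points] set.
#' @return An object of class `emg_metrics`: list with `onset_tpr`,
#'   `offset_tpr` (fractions), `f1` (0-100), `onset_bias_ms`,
#'   `offset_bias_ms`, `counts`, `n_true`, `n_detected`.
#' @export
compute_metrics <- function(classification, truth) {
  cn <- classification$counts
  pr <- classification$pairs
  n_true <- c(onset = sum(truth$event == "onset"),
              offset = sum(truth$event == "offset"))
  tpr <- function(type) {
    if (n_true[[type]] == 0L) return(NA_real_)
    cn[type, "TP"] / n_true[[type]]
  }
  bias <- function(type) {
    d <- pr[pr$event == type, ]
    if (!nrow(d)) return(NA_real_)
    sqrt(mean(((d$detected_s - d$true_s) * 1000)^2))
  }
  denom <- 2 * cn["pooled", "TP"] + cn["pooled", "FN"] + cn["pooled", "FP"]
  f1 <- if (denom > 0) 2 * cn["pooled", "TP"] / denom * 100 else NA_real_
  structure(list(onset_tpr = tpr("onset"), offset_tpr = tpr("offset"),
                 f1 = f1, onset_bias_ms = bias("onset"),
                 offset_bias_ms = bias("offset"), counts = cn,
                 n_true = n_true, n_detected = classification$n_detected),
            class = "emg_metrics")
}

#' Score a detection against ground truth
#'
#' One-call wrapper: [build_regions] -> [classify_events] ->
#' [compute_metrics].
#'
#' @param detected An `emg_detection` object or a [change_points] set.
#' @param truth Ground truth: an `emg_recording` or a [change_points] set.
#' @param duration Recording length in seconds (taken from the detection
#'   or recording object when available).
#' @param pre_ms,post_ms Valid-interval extents (ms); see [build_regions].
#' @return An `emg_metrics` object.
#' @examples
#' rec <- simulate_emg(duration = 15, n_bursts = 4, seed = 3)
#' evaluate_detection(meonnd(rec), rec)
#' @export
evaluate_detection <- function(detected, truth, duration = NULL,
                               pre_ms = 300, post_ms = 200) {
  if (inherits(detected, "emg_detection")) {
    if (is.null(duration)) duration <- detected$n / detected$fs
    detected <- detected$events
  }
  if (inherits(truth, "emg_recording")) {
    if (is.null(duration)) duration <- length(truth$signal) / truth$fs
    truth <- truth$truth
  }
  if (is.null(duration)) stop("'duration' is required", call. = FALSE)
  regions <- build_regions(truth, duration, pre_ms, post_ms)
  compute_metrics(classify_events(detected, regions), truth)
}

#' @export
print.emg_metrics <- function(x, ...) {
  fmt <- function(v, pct = FALSE) {
    if (is.na(v)) "NA" else if (pct) sprintf("%.2f%%", 100 * v) else
      sprintf("%.1f", v)
  }
  cat("<emg_metrics>\n")
  cat(sprintf("  Onset TPR  %s   Offset TPR %s   F1 %s\n",
              fmt(x$onset_tpr, TRUE), fmt(x$offset_tpr, TRUE),
              if (is.na(x$f1)) "NA" else sprintf("%.2f", x$f1)))
  cat(sprintf("  Onset bias %s ms   Offset bias %s ms\n",
              fmt(x$onset_bias_ms), fmt(x$offset_bias_ms)))
  cat("  pooled counts: ",
      paste(colnames(x$counts),
            x$counts["pooled", ], sep = "=", collapse = " "), "\n")
  invisible(x)
}
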