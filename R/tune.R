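#' Default parameter traversal grids
#'
#' The exhaustive-search ranges for the two monitors: MTEO scale `k` odd in
#' 1-41, median window `L` odd in 3-83 (the `L = 2k + 1` pairing motivates
#' the range), threshold factor `j` in 1-10 for MEOTD, and classifier
#' threshold `T` in 0.406, 0.426, ..., 0.506 for MEONND (step 0.02 from
#' 0.406; the nominal endpoint 0.514 is not reachable with that step and
#' is excluded).
#'
#' @param method `"meotd"` or `"meonnd"`.
#' @return Data frame with one row per grid cell (columns `k`, `L` and `j`
#'   or `threshold`).
#' @export
default_grid <- function(method = c("meotd", "meonnd")) {
  method <- match.arg(method)
  k <- seq(1L, 41L, by = 2L)
  L <- seq(3L, 83L, by = 2L)
  if (method == "meotd") {
    expand.grid(k = k, L = L, j = 1:10, KEEP.OUT.ATTRS = FALSE)
  } else {
    expand.grid(k = k, L = L, threshold = seq(0.406, 0.514, by = 0.02),
                KEEP.OUT.ATTRS = FALSE)
  }
}

# Micro-averaged metrics of one parameter cell over a list of recordings.
cell_metrics <- function(recordings, method, cell, detector_args) {
  counts <- NULL
  pairs <- list()
  n_true <- c(onset = 0L, offset = 0L)
  n_det <- c(onset = 0L, offset = 0L)
  for (rec in recordings) {
    args <- c(list(rec), as.list(cell), detector_args)
    names(args)[2:(1 + length(cell))] <-
      ifelse(names(cell) == "k", "k_max", names(cell))
    fit <- do.call(method, args)
    duration <- length(rec$signal) / rec$fs
    cls <- classify_events(fit$events,
                           build_regions(rec$truth, duration))
    counts <- if (is.null(counts)) cls$counts else counts + cls$counts
    pairs[[length(pairs) + 1L]] <- cls$pairs
    n_true <- n_true + c(onset = sum(rec$truth$event == "onset"),
                         offset = sum(rec$truth$event == "offset"))
    n_det <- n_det + cls$n_detected
  }
  pooled <- structure(list(counts = counts, pairs = do.call(rbind, pairs),
                           n_detected = n_det),
                      class = "confusion_counts")
  truth_stub <- change_points(rep(c("onset", "offset"), n_true["onset"]),
                              seq_len(2 * n_true["onset"]))
  compute_metrics(pooled, truth_stub)
}

#' Exhaustive AHP-scored parameter search
#'
#' Runs a detector at every cell of a parameter grid over a corpus of
#' labelled recordings, micro-averages the region-classified confusion
#' counts (biases pooled over all matched pairs), scores each cell with
#' [ahp_score], and returns the argmax. Ties are broken toward smaller
#' parameter values in column order. A cell where the detector fails is
#' scored `NA` with a warning and the search continues.
#'
#' @param recordings List of `emg_recording` objects (or a single one).
#' @param method `"meotd"` or `"meonnd"`.
#' @param grid Data frame of parameter cells; defaults to
#'   [default_grid]. Column `k` is passed to the detector as `k_max`.
#' @param weights AHP weights for [ahp_score].
#' @param ... Fixed extra arguments passed to every detector call.
#' @return An object of class `emg_tuning`: list with `table` (the grid
#'   with an appended `score` column), `best` (the winning row) and
#'   `best_metrics`.
#' @examples
#' recs <- lapply(1:2, function(s) simulate_emg(duration = 15, n_bursts = 3,
#'                                              seed = s))
#' tune_detector(recs, "meonnd",
#'               grid = expand.grid(k = 15, L = 15,
#'                                  threshold = c(0.466, 0.506)))
#' @export
tune_detector <- function(recordings, method = c("meotd", "meonnd"),
                          grid = default_grid(method),
                          weights = ahp_weights(), ...) {
  method <- match.arg(method)
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  if (!length(recordings)) stop("no recordings supplied", call. = FALSE)
  if (!nrow(grid)) stop("empty parameter grid", call. = FALSE)
  detector_args <- list(...)
  scores <- rep(NA_real_, nrow(grid))
  best_metrics <- NULL
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, , drop = FALSE]
    m <- tryCatch(cell_metrics(recordings, method, cell, detector_args),
                  error = function(e) {
                    warning(sprintf("grid cell %d failed: %s", i,
                                    conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (is.null(m)) next
    scores[i] <- tryCatch(ahp_score(m, weights), error = function(e) NA_real_)
  }
  tab <- cbind(grid, score = scores)
  if (all(is.na(scores))) stop("every grid cell failed", call. = FALSE)
  # argmax with lexicographic tie-break toward smaller parameters
  ord <- do.call(order, c(list(-scores), as.list(grid)))
  best_i <- ord[1L]
  best_metrics <- cell_metrics(recordings, method,
                               grid[best_i, , drop = FALSE], detector_args)
  structure(list(table = tab, best = tab[best_i, , drop = FALSE],
                 best_metrics = best_metrics, method = method),
            class = "emg_tuning")
}

#' @export
print.emg_tuning <- function(x, ...) {
  cat(sprintf("<emg_tuning> %s over %d grid cells\n", toupper(x$method),
              nrow(x$table)))
  cat("best cell:\n")
  print(x$best, row.names = FALSE)
  print(x$best_metrics)
  invisible(x)
}
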