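#' Pairwise judgment matrix over the five detection metrics
#'
#' The default 5x5 reciprocal matrix on the 1-5 scale comparing Onset TPR,
#' Offset TPR, F1 Score, Onset bias and Offset bias: the two TPRs dominate
#' F1 (2:1) and both biases (3:1); F1 dominates the biases (2:1).
#' Off-diagonal reciprocals are exact fractions (1/2, 1/3).
#'
#' @return A 5x5 named numeric matrix.
#' @export
judgment_matrix <- function() {
  nm <- c("onset_tpr", "offset_tpr", "f1", "onset_bias", "offset_bias")
  m <- rbind(c(1, 1, 2, 3, 3),
             c(1, 1, 2, 3, 3),
             c(1 / 2, 1 / 2, 1, 2, 2),
             c(1 / 3, 1 / 3, 1 / 2, 1, 1),
             c(1 / 3, 1 / 3, 1 / 2, 1, 1))
  dimnames(m) <- list(nm, nm)
  m
}

# Random consistency indices; RI(5) follows the printed convention 1.11
# (some tables use 1.12).
ahp_ri <- c(0, 0, 0.58, 0.90, 1.11, 1.24, 1.32, 1.41, 1.45, 1.49)

#' AHP criterion weights and consistency statistics
#'
#' Weights are derived by the row-geometric-mean method: the unnormalized
#' eigenvector is the geometric mean of each row, normalized to sum 1.
#' The maximum eigenvalue is estimated as the mean of the component-wise
#' ratios `(A w)_i / w_i`; consistency index `CI = (lambda_max - n) /
#' (n - 1)` and consistency ratio `CR = CI / RI(n)`. `CR < 0.1` is the
#' usual acceptance rule for a judgment matrix.
#'
#' @param A Square positive reciprocal matrix (pairwise comparisons);
#'   reciprocity is checked to a 1e-3 tolerance so rounded entries such as
#'   0.3333 are accepted.
#' @return An object of class `ahp_weights`: list with `eigenvector` (row
#'   geometric means), `weights` (normalized, sum 1), `lambda_max`, `ci`,
#'   `ri`, `cr` and `n`.
#' @examples
#' ahp_weights(judgment_matrix())
#' @export
ahp_weights <- function(A = judgment_matrix()) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n || n < 2L) stop("'A' must be square (n >= 2)",
                                   call. = FALSE)
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("'A' must be strictly positive", call. = FALSE)
  }
  if (any(abs(diag(A) - 1) > 1e-9)) {
    stop("'A' must have unit diagonal", call. = FALSE)
  }
  if (any(abs(A * t(A) - 1) > 1e-3 * A * t(A))) {
    stop("'A' is not reciprocal (a_ji must equal 1/a_ij)", call. = FALSE)
  }
  gm <- exp(rowMeans(log(A)))
  w <- gm / sum(gm)
  lambda <- mean(as.vector(A %*% w) / w)
  ci <- (lambda - n) / (n - 1)
  ri <- if (n <= length(ahp_ri)) ahp_ri[n] else ahp_ri[length(ahp_ri)]
  cr <- if (ri > 0) ci / ri else 0
  structure(list(eigenvector = gm, weights = w, lambda_max = lambda,
                 ci = ci, ri = ri, cr = cr, n = n),
            class = "ahp_weights")
}

#' @export
print.ahp_weights <- function(x, ...) {
  cat(sprintf("<ahp_weights> n=%d  lambda_max=%.4f  CI=%.4f  RI=%.2f  CR=%.3f%s\n",
              x$n, x$lambda_max, x$ci, x$ri, x$cr,
              if (x$cr < 0.1) " (consistent)" else " (INCONSISTENT)"))
  print(round(rbind(eigenvector = x$eigenvector, weight = x$weights), 4))
  invisible(x)
}

#' Composite AHP score of a detection-metrics report
#'
#' `score = w1 * OnsetTPR + w2 * OffsetTPR + w3 * F1 - w4 * OnsetBias/1e5
#' - w5 * OffsetBias/1e5`, with the TPRs and F1 as fractions in `[0, 1]`
#' and the biases in milliseconds. The `1e5` divisor confines the bias
#' terms to the 3rd-4th decimal so they perturb rather than dominate the
#' rate terms; the sign flip makes larger bias worse. Higher scores are
#' better.
#'
#' @param metrics An `emg_metrics` object, or a list/vector with elements
#'   `onset_tpr`, `offset_tpr` (fractions), `f1` (0-100 scale),
#'   `onset_bias_ms`, `offset_bias_ms`.
#' @param weights An `ahp_weights` object or a numeric vector of 5 weights
#'   (onset TPR, offset TPR, F1, onset bias, offset bias).
#' @return Single numeric score.
#' @examples
#' ahp_score(list(onset_tpr = 0.9731, offset_tpr = 0.9333, f1 = 93.48,
#'                onset_bias_ms = 103, offset_bias_ms = 209))
#' @export
ahp_score <- function(metrics, weights = ahp_weights()) {
  w <- if (inherits(weights, "ahp_weights")) weights$weights else
    as.numeric(weights)
  if (length(w) != 5L) stop("five weights are required", call. = FALSE)
  need <- c("onset_tpr", "offset_tpr", "f1", "onset_bias_ms",
            "offset_bias_ms")
  vals <- vapply(need, function(f) {
    v <- metrics[[f]]
    if (is.null(v) || is.na(v)) {
      stop(sprintf("metric '%s' is missing; the AHP score is undefined", f),
           call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1))
  unname(vals[1] * w[1] + vals[2] * w[2] + (vals[3] / 100) * w[3] -
           vals[4] / 1e5 * w[4] - vals[5] / 1e5 * w[5])
}
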