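## Synchrony metrics: the Level of Synchronicity (LoS) — a time-averaged
## Gaussian kernel of pairwise voltage differences, 1 for identical signals
## and ~0.61 at a constant offset of one kernel width — the Phase Locking
## Value (PLV) on analytic-signal phases, the idealized block matrix of a
## partition, and the agreement scores used to compare a simulation's LoS
## against the partition's prediction.

window_index <- function(result, window) {
  tmax <- max(result$time)
  if (window > tmax + 1e-12) stop("window (", window, " s) longer than simulation (",
                                  tmax, " s)")
  which(result$time >= tmax - window - 1e-12)
}

#' Level-of-Synchronicity matrix
#'
#' `LoS_ij` is the average over the analysis window of
#' `exp(-(V_i(t) - V_j(t))^2 / (2 sigma^2))`: symmetric, unit diagonal,
#' entries in `[0, 1]`.
#'
#' @param result a `simulation_result` (or plain nodes x time matrix with a
#'   `time` attribute)
#' @param window trailing analysis window (s), default the last 1 s
#' @param sigma kernel scale (V), default 0.1 mV
#' @return a `synchrony_matrix` (square, node-named), metric `"LoS"`
#' @export
los_matrix <- function(result, window = 1, sigma = 0.1e-3) {
  idx <- window_index(result, window)
  V <- result$V[, idx, drop = FALSE]
  n <- nrow(V)
  M <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- V[i, ] - V[j, ]
      M[i, j] <- M[j, i] <- mean(exp(-d^2 / (2 * sigma^2)))
    }
  }
  dimnames(M) <- list(rownames(V), rownames(V))
  structure(M, metric = "LoS", window = window, sigma = sigma,
            class = c("synchrony_matrix", "matrix"))
}

#' Phase-Locking-Value matrix
#'
#' Signals are de-meaned over the window; instantaneous phases come from the
#' analytic signal (spectral Hilbert transform); `PLV_ij` is the magnitude of
#' the time-averaged unit phasor of the phase difference. A pair of
#' identical constant signals scores 1; a pair involving one constant,
#' non-identical signal has no defined phase and is reported as 0 with the
#' pair recorded in the `flagged` attribute.
#'
#' @inheritParams los_matrix
#' @return a `synchrony_matrix`, metric `"PLV"`
#' @export
plv_matrix <- function(result, window = 1) {
  idx <- window_index(result, window)
  V <- result$V[, idx, drop = FALSE]
  n <- nrow(V)
  centered <- V - rowMeans(V)
  const <- apply(centered, 1, function(x) max(abs(x)) < 1e-15)
  phases <- matrix(NA_real_, n, ncol(V))
  for (i in seq_len(n)) if (!const[i]) phases[i, ] <- Arg(analytic_signal(centered[i, ]))
  M <- diag(1, n)
  flagged <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (const[i] || const[j]) {
        same <- max(abs(V[i, ] - V[j, ])) < 1e-15
        M[i, j] <- M[j, i] <- if (same) 1 else 0
        if (!same) flagged <- c(flagged, paste(rownames(V)[i], rownames(V)[j], sep = "~"))
      } else {
        M[i, j] <- M[j, i] <- Mod(mean(exp(1i * (phases[i, ] - phases[j, ]))))
      }
    }
  }
  dimnames(M) <- list(rownames(V), rownames(V))
  structure(M, metric = "PLV", window = window, flagged = flagged,
            class = c("synchrony_matrix", "matrix"))
}

## analytic signal via FFT (positive frequencies doubled)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Idealized synchrony matrix of a partition
#'
#' Block matrix with 1 inside every cell and 0 across cells: the LoS pattern
#' a perfectly fiber-synchronized, fiber-separated simulation would produce.
#'
#' @param coloring a `coloring`
#' @param order optional node order (default lexicographic)
#' @return a `synchrony_matrix`, metric `"ideal"`
#' @export
ideal_matrix <- function(coloring, order = NULL) {
  nm <- if (is.null(order)) sort(names(coloring)) else order
  col <- coloring[nm]
  M <- outer(col, col, `==`) * 1
  dimnames(M) <- list(nm, nm)
  structure(M, metric = "ideal", class = c("synchrony_matrix", "matrix"))
}

#' Agreement between a measured LoS matrix and the partition's ideal
#'
#' The LoS matrix is binarized (entries at least `1 - binarize_tol` become 1,
#' everything lower becomes 0) and subtracted from the ideal matrix; the sum
#' of off-diagonal differences is divided by `2 (n^2 - n)`. Zero means
#' perfect agreement; negative values mean extra cross-fiber synchrony
#' (fibers synchronizing with each other — not a failure of the partition);
#' positive values mean expected within-fiber synchrony was not found.
#'
#' @param los measured `synchrony_matrix`
#' @param ideal idealized matrix from [ideal_matrix()]
#' @param binarize_tol closeness to 1 required to count as synchronized
#' @return scalar score
#' @export
agreement_score <- function(los, ideal, binarize_tol = 1e-3) {
  if (!identical(rownames(los), rownames(ideal))) {
    if (is.null(rownames(los)) || !setequal(rownames(los), rownames(ideal))) {
      stop("node order mismatch between LoS and ideal matrices")
    }
    ideal <- ideal[rownames(los), rownames(los)]
  }
  n <- nrow(los)
  B <- (los >= 1 - binarize_tol) * 1
  diff <- (unclass(ideal) - B)
  diag(diff) <- 0
  sum(diff) / (2 * (n^2 - n))
}

#' Masked within-fiber synchrony difference
#'
#' Mean, over the within-cell off-diagonal entries selected by the coloring,
#' of `mask - averaged`. Used to score how much within-fiber LoS survives a
#' weight-perturbation sweep relative to the unperturbed (masking) run.
#'
#' @param averaged averaged `synchrony_matrix` over perturbation replicates
#' @param mask binarized reference matrix (same node order)
#' @param coloring the fiber `coloring` defining the diagonal blocks
#' @return scalar; 0 when the averaged matrix equals the mask on the blocks
#' @export
masked_difference <- function(averaged, mask, coloring) {
  if (!identical(dim(averaged), dim(mask))) stop("shape mismatch")
  nm <- rownames(averaged)
  col <- coloring[nm]
  same_cell <- outer(col, col, `==`)
  sel <- same_cell & !diag(TRUE, nrow(averaged))
  if (!any(sel)) return(0)
  mean((unclass(mask) - unclass(averaged))[sel])
}

#' @export
print.synchrony_matrix <- function(x, ...) {
  cat(sprintf("synchrony_matrix (%s): %d nodes, range [%.3g, %.3g]\n",
              attr(x, "metric"), nrow(x), min(x), max(x)))
  invisible(x)
}
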