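# SPXY calibration/validation partitioning: Kennard-Stone-style greedy
# max-min selection on a joint, max-normalised spectral (X) plus response
# (Y) distance. Deterministic; ties break toward the smallest index.

#' Joint X-Y sample distance matrix
#'
#' `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)` with `dx` the Euclidean
#' distance between spectra and `dy` the absolute response difference.
#' A term whose maximum is zero (e.g. all labels equal) is dropped, which
#' for the Y term reduces the split to plain Kennard-Stone behaviour.
#'
#' @param X numeric N x L matrix (rows = samples), finite entries, N >= 2.
#' @param y numeric response vector of length N (binary adulteration status
#'   in this package's use).
#' @return symmetric N x N matrix with zero diagonal.
#' @export
combined_distance <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  if (length(y) != n) stop("y must have one value per row of X", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  dx <- as.matrix(stats::dist(X, method = "euclidean"))
  dy <- abs(outer(y, y, "-"))
  d <- matrix(0, n, n)
  if (max(dx) > 0) d <- d + dx / max(dx)
  if (max(dy) > 0) d <- d + dy / max(dy)
  dimnames(d) <- NULL
  d
}

#' SPXY calibration/validation split
#'
#' Greedy max-min selection on [combined_distance()]: seed with the pair at
#' maximal joint distance, then repeatedly add the unselected sample whose
#' minimum distance to the selected set is largest, until
#' `ceiling(ratio * N)` calibration samples are chosen. The remainder forms
#' the validation set. Fully deterministic; all ties break toward the
#' smallest sample index. Once selected for calibration a sample never
#' moves, so the two subsets are disjoint by construction.
#'
#' @param x a [spectra_set()] (spectra = X, labels = Y), or a numeric
#'   matrix with `y` supplied separately.
#' @param ratio calibration fraction in (0, 1); default 0.75.
#' @param y response vector, only when `x` is a matrix.
#' @return an object of class `spxy_split`: list with `calibration_idx`
#'   (in selection order), `validation_idx` (ascending) and `ratio`.
#' @export
spxy_split <- function(x, ratio = 0.75, y = NULL) {
  if (inherits(x, "spectra_set")) {
    X <- x$absorbance
    y <- as.numeric(x$labels)
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop("y is required when x is a matrix", call. = FALSE)
  }
  if (length(ratio) != 1L || !is.finite(ratio) || ratio <= 0 || ratio >= 1) {
    stop("ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(X)
  if (n < 2L) stop("need at least two samples to split", call. = FALSE)
  d <- combined_distance(X, y)
  n_cal <- as.integer(ceiling(ratio * n))

  # seed pair: maximal joint distance, smallest (i, j) on ties
  m <- max(d)
  cand <- which(d == m, arr.ind = TRUE)
  cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  sel <- as.integer(cand[1L, ])

  if (n_cal <= 1L) {
    sel <- sel[1L]
  } else {
    while (length(sel) < n_cal) {
      rest <- setdiff(seq_len(n), sel)
      mind <- apply(d[rest, sel, drop = FALSE], 1L, min)
      sel <- c(sel, rest[which.max(mind)])
    }
  }
  structure(list(calibration_idx = sel,
                 validation_idx = setdiff(seq_len(n), sel),
                 ratio = ratio),
            class = "spxy_split")
}

#' @export
print.spxy_split <- function(x, ...) {
  cat(sprintf("<spxy_split> %d calibration / %d validation (ratio %.2f)\n",
              length(x$calibration_idx), length(x$validation_idx), x$ratio))
  invisible(x)
}
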