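# Numeric kernels for the 1-D network: convolution (im2col + BLAS matrix
# product), max-pooling, ReLU/sigmoid, squeeze-and-excitation, dense
# layers. Each .xxx_forward returns list(out, cache); the matching
# .xxx_backward consumes the upstream gradient and the cache. Feature maps
# are 3-D arrays C x T x B (channels, positions, batch); weights are
# arrays C_out x C_in x k.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.as_cmap <- function(x) {
  # Accept a C x T matrix (single sample) or a C x T x B array.
  if (is.matrix(x)) array(x, c(dim(x), 1L))
  else if (is.array(x) && length(dim(x)) == 3L) x
  else if (is.numeric(x) && is.null(dim(x))) array(x, c(1L, length(x), 1L))
  else stop("expected a vector, C x T matrix or C x T x B array", call. = FALSE)
}

.conv1d_forward <- function(x, W, b = NULL, pad = 0L) {
  d <- dim(x); c_in <- d[1L]; t_in <- d[2L]; bsz <- d[3L]
  dw <- dim(W); c_out <- dw[1L]; k <- dw[3L]
  if (dw[2L] != c_in) stop("kernel bank expects ", dw[2L],
                           " input channels, got ", c_in, call. = FALSE)
  t_out <- t_in + 2L * pad - k + 1L
  if (t_out < 1L) stop("input length ", t_in, " too short for kernel size ",
                       k, call. = FALSE)
  if (k == 1L && pad == 0L) {
    P <- x
    dim(P) <- c(c_in, t_out * bsz)
  } else {
    P <- .im2col_pad(x, c_in, t_in, bsz, k, pad)
  }
  Wm <- matrix(W, c_out, c_in * k)
  y <- Wm %*% P
  if (!is.null(b)) y <- y + b
  dim(y) <- c(c_out, t_out, bsz)
  list(out = y,
       cache = list(P = P, Wm = Wm, dims = c(c_in = c_in, t_in = t_in,
                                             bsz = bsz, c_out = c_out, k = k,
                                             pad = pad, t_out = t_out),
                    has_bias = !is.null(b)))
}

.conv1d_backward <- function(dout, cache) {
  dm <- cache$dims
  dY <- matrix(dout, dm[["c_out"]], dm[["t_out"]] * dm[["bsz"]])
  dWm <- tcrossprod(dY, cache$P)                    # c_out x (c_in*k)
  dW <- array(dWm, c(dm[["c_out"]], dm[["c_in"]], dm[["k"]]))
  db <- if (cache$has_bias) rowSums(dY) else NULL
  dP <- crossprod(cache$Wm, dY)                     # (c_in*k) x (t_out*bsz)
  if (dm[["k"]] == 1L && dm[["pad"]] == 0L) {
    dx <- dP
    dim(dx) <- c(dm[["c_in"]], dm[["t_in"]], dm[["bsz"]])
  } else {
    dx <- .col2im_pad(dP, dm[["c_in"]], dm[["t_in"]], dm[["bsz"]],
                      dm[["k"]], dm[["pad"]])
  }
  list(dx = dx, dW = dW, db = db)
}

.maxpool_forward <- function(x, size = 2L, stride = 2L) {
  if (size != stride) {
    stop("only non-overlapping pooling (size == stride) is supported",
         call. = FALSE)
  }
  d <- dim(x); C <- d[1L]; t_in <- d[2L]; bsz <- d[3L]
  if (t_in %/% size < 1L) {
    stop("temporal length ", t_in, " shorter than pool size ", size,
         call. = FALSE)
  }
  res <- .maxpool_fwd(x, C, t_in, bsz, as.integer(size))
  list(out = res$out, cache = list(idx = res$idx, size = as.integer(size),
                                   t_in = t_in, C = C, bsz = bsz))
}

.maxpool_backward <- function(dout, cache) {
  .maxpool_bwd(dout, cache$idx, cache$C, cache$t_in, cache$bsz, cache$size)
}

.relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
.relu_backward <- function(dout, cache) dout * cache

# Squeeze-and-excitation: per-channel global average pooling, bottleneck
# C -> C/r (ReLU) -> C (sigmoid), then channel-wise reweighting of x.
.se_forward <- function(x, W1, b1, W2, b2) {
  d <- dim(x); C <- d[1L]; t_in <- d[2L]; bsz <- d[3L]
  s <- colSums(aperm(x, c(2L, 1L, 3L))) / t_in        # C x B channel means
  dim(s) <- c(C, bsz)
  z1 <- W1 %*% s + b1
  a1 <- pmax(z1, 0)
  z2 <- W2 %*% a1 + b2
  g <- .sigmoid(z2)                                   # C x B gates in (0,1)
  gfull <- g[, rep(seq_len(bsz), each = t_in), drop = FALSE]
  dim(gfull) <- c(C, t_in, bsz)
  list(out = x * gfull,
       cache = list(x = x, s = s, z1 = z1, a1 = a1, g = g, gfull = gfull,
                    W1 = W1, W2 = W2, t_in = t_in))
}

.se_backward <- function(dout, cache) {
  C <- nrow(cache$g); bsz <- ncol(cache$g); t_in <- cache$t_in
  dx <- dout * cache$gfull
  dg <- colSums(aperm(dout * cache$x, c(2L, 1L, 3L)))  # C x B
  dim(dg) <- c(C, bsz)
  dz2 <- dg * cache$g * (1 - cache$g)
  dW2 <- tcrossprod(dz2, cache$a1)
  db2 <- rowSums(dz2)
  da1 <- crossprod(cache$W2, dz2)
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- tcrossprod(dz1, cache$s)
  db1 <- rowSums(dz1)
  ds <- crossprod(cache$W1, dz1) / t_in                # spread over positions
  dsf <- ds[, rep(seq_len(bsz), each = t_in), drop = FALSE]
  dim(dsf) <- c(C, t_in, bsz)
  dx <- dx + dsf
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

.dense_forward <- function(x, W, b) {
  list(out = W %*% x + b, cache = list(x = x, W = W))
}

.dense_backward <- function(dout, cache) {
  list(dx = crossprod(cache$W, dout),
       dW = tcrossprod(dout, cache$x),
       db = rowSums(dout))
}

#' Valid (unpadded) 1-D convolution
#'
#' Cross-correlation without padding, stride 1:
#' `y_j(t) = sum_i sum_c x_c(t+i) * W[j, c, i+1] + b_j` for
#' `1 <= t <= n - k + 1`, so an input of length `n` and a kernel of size
#' `k` yield an output of length `n - k + 1`.
#'
#' @param x input feature map: a numeric vector (one channel), or a
#'   `C_in x n` matrix.
#' @param W kernel bank: a numeric vector of `k` taps (one-in, one-out
#'   channel) or an array `C_out x C_in x k`.
#' @param bias optional `C_out` bias vector (default none).
#' @return `C_out x (n - k + 1)` matrix.
#' @export
conv1d_valid <- function(x, W, bias = NULL) {
  xarr <- .as_cmap(x)
  if (is.null(dim(W))) W <- array(W, c(1L, 1L, length(W)))
  out <- .conv1d_forward(xarr, W, bias, pad = 0L)$out
  matrix(out, dim(out)[1L], dim(out)[2L])
}

#' Squeeze-and-excitation channel recalibration
#'
#' Squeeze: per-channel mean over positions. Excitation: fully connected
#' `C -> C/r` with ReLU then `C/r -> C` with sigmoid. Reweight: multiply
#' each channel of `x` by its gate, which lies strictly in (0, 1).
#'
#' @param x `C x T` matrix (or `C x T x B` array).
#' @param params list with `W1` (`C/r x C`), `b1`, `W2` (`C x C/r`), `b2`.
#' @return recalibrated feature map, same shape as `x`.
#' @export
se_recalibrate <- function(x, params) {
  xarr <- .as_cmap(x)
  out <- .se_forward(xarr, params$W1, params$b1, params$W2, params$b2)$out
  if (is.matrix(x)) matrix(out, dim(out)[1L], dim(out)[2L]) else out
}
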