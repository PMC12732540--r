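# The multi-scale attention fusion network. Pipeline:
#   SPM  : valid 1-D convolution + max-pooling (learned preprocessing; the
#          only preprocessing applied to raw absorbance)
#   MSFEM: n parallel branches of d stacked feature extraction blocks
#          (same-padded conv -> ReLU -> squeeze-and-excitation -> max-pool),
#          one kernel size per branch so all branches stay length-aligned
#   CSAFM: for every reference scale r, concatenate (X_r, X_j) channel-wise,
#          derive sigmoid attention a_j = sigma(conv2(relu(conv1(Z_j)))),
#          recalibrate X_j and sum the recalibrated partners onto X_r
#   head : flatten + concatenate all fused maps -> dense ReLU layer ->
#          single sigmoid unit (adulteration probability)

#' SPM (spectral preprocessing) configuration
#'
#' @param kernel_size valid-convolution kernel width (default 16).
#' @param out_channels output channels (default 64).
#' @param pool_size,pool_stride max-pooling window (non-overlapping).
#' @export
spm_config <- function(kernel_size = 16, out_channels = 64,
                       pool_size = 2, pool_stride = 2) {
  stopifnot(kernel_size >= 1, out_channels >= 1, pool_size == pool_stride)
  structure(list(kernel_size = as.integer(kernel_size),
                 out_channels = as.integer(out_channels),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride)),
            class = "spm_config")
}

#' MSFEM (multi-scale feature extraction) configuration
#'
#' @param kernel_sizes 1 to 3 odd kernel widths, one per parallel branch
#'   (default `c(1, 5, 9)`, the tri-scale setting).
#' @param depth number of stacked feature extraction blocks per branch,
#'   1 to 3 (default 2). Stacked blocks reuse the branch's kernel size.
#' @param channels feature channels per block (default 64).
#' @param se_reduction squeeze-and-excitation bottleneck ratio; must divide
#'   `channels` (default 8).
#' @param pool_size,pool_stride max-pooling window per block.
#' @export
msfem_config <- function(kernel_sizes = c(1, 5, 9), depth = 2, channels = 64,
                         se_reduction = 8, pool_size = 2, pool_stride = 2) {
  kernel_sizes <- as.integer(kernel_sizes)
  n <- length(kernel_sizes)
  if (n < 1L || n > 3L) stop("between 1 and 3 branches supported", call. = FALSE)
  if (any(kernel_sizes < 1L) || any(kernel_sizes %% 2L == 0L)) {
    stop("branch kernel sizes must be odd (same-padding keeps branches aligned)",
         call. = FALSE)
  }
  if (!depth %in% 1:3) stop("depth must be 1, 2 or 3", call. = FALSE)
  if (channels %% se_reduction != 0) {
    stop("channels must be divisible by se_reduction", call. = FALSE)
  }
  stopifnot(pool_size == pool_stride)
  structure(list(kernel_sizes = kernel_sizes, depth = as.integer(depth),
                 channels = as.integer(channels),
                 se_reduction = as.integer(se_reduction),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride)),
            class = "msfem_config")
}

#' CSAFM (cross-scale attention fusion) configuration
#'
#' Both fusion convolutions default to kernel size 1 (pure channel mixers:
#' 2C -> hidden, then hidden -> C), with one parameter set per ordered
#' (reference, partner) pair.
#'
#' @param hidden_channels width after the first fusion convolution;
#'   `NULL` means "same as the MSFEM channels".
#' @param kernel1,kernel2 odd kernel sizes of the two fusion convolutions.
#' @export
csafm_config <- function(hidden_channels = NULL, kernel1 = 1, kernel2 = 1) {
  if (!is.null(hidden_channels)) stopifnot(hidden_channels >= 1)
  stopifnot(kernel1 %% 2 == 1, kernel2 %% 2 == 1)
  structure(list(hidden_channels = if (is.null(hidden_channels)) NULL
                 else as.integer(hidden_channels),
                 kernel1 = as.integer(kernel1), kernel2 = as.integer(kernel2)),
            class = "csafm_config")
}

#' Full network configuration
#'
#' @param input_length number of spectral points L (default 267, the
#'   900-1698 nm / 3 nm grid).
#' @param spm,msfem,csafm module configurations.
#' @param head_hidden width of the hidden dense layer (default 128).
#' @return an object of class `smafnet_config`.
#' @export
smafnet_config <- function(input_length = 267, spm = spm_config(),
                           msfem = msfem_config(), csafm = csafm_config(),
                           head_hidden = 128) {
  stopifnot(inherits(spm, "spm_config"), inherits(msfem, "msfem_config"),
            inherits(csafm, "csafm_config"), head_hidden >= 1)
  cfg <- structure(list(input_length = as.integer(input_length), spm = spm,
                        msfem = msfem, csafm = csafm,
                        head_hidden = as.integer(head_hidden)),
                   class = "smafnet_config")
  sh <- smafnet_shapes(cfg)   # errors if any stage collapses to length < 1
  if (sh$flat_width < 1L) stop("flattened width must be positive", call. = FALSE)
  cfg
}

#' Shape trace of a configuration
#'
#' @param cfg a [smafnet_config()].
#' @return list with the temporal length after the SPM, after each block
#'   depth, and the flattened head input width.
#' @export
smafnet_shapes <- function(cfg) {
  l <- cfg$input_length
  t_conv <- l - cfg$spm$kernel_size + 1L
  if (t_conv < 1L) stop("input shorter than the SPM kernel", call. = FALSE)
  t_spm <- t_conv %/% cfg$spm$pool_size
  if (t_spm < 1L) stop("SPM pooling collapses the sequence", call. = FALSE)
  t <- t_spm
  t_depth <- integer(cfg$msfem$depth)
  for (l2 in seq_len(cfg$msfem$depth)) {
    t <- t %/% cfg$msfem$pool_size
    if (t < 1L) stop("MSFEM pooling collapses the sequence", call. = FALSE)
    t_depth[l2] <- t
  }
  n <- length(cfg$msfem$kernel_sizes)
  list(t_spm_conv = t_conv, t_spm = t_spm, t_depth = t_depth, t_final = t,
       flat_width = n * cfg$msfem$channels * t)
}

.csafm_hidden <- function(cfg) {
  if (is.null(cfg$csafm$hidden_channels)) cfg$msfem$channels
  else cfg$csafm$hidden_channels
}

# ---- parameter tree utilities -------------------------------------------

.tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1L]]
  if (is.numeric(t1)) return(do.call(f, trees))
  nm <- names(t1)
  out <- lapply(seq_along(t1), function(i) {
    # align parallel trees by name where names exist, by position otherwise
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
    do.call(.tree_map, c(list(f), lapply(trees, `[[`, key)))
  })
  names(out) <- nm
  out
}

.tree_leaves <- function(tree, prefix = character(0)) {
  if (is.numeric(tree)) {
    out <- list(tree)
    names(out) <- paste(prefix, collapse = ".")
    return(out)
  }
  nm <- names(tree)
  if (is.null(nm)) nm <- as.character(seq_along(tree))
  do.call(c, lapply(seq_along(tree), function(i) {
    .tree_leaves(tree[[i]], c(prefix, nm[i]))
  }))
}

#' Number of learnable parameters
#' @param params a `smafnet_params` object (or a raw weight tree).
#' @export
n_parameters <- function(params) {
  wt <- if (inherits(params, "smafnet_params")) params$weights else params
  sum(vapply(.tree_leaves(wt), length, integer(1)))
}

.unwrap_weights <- function(params) {
  if (inherits(params, "smafnet_params")) params$weights else params
}

# ---- initialization ------------------------------------------------------

.init_conv <- function(c_out, c_in, k) {
  a <- 1 / sqrt(c_in * k)
  list(W = array(stats::runif(c_out * c_in * k, -a, a), c(c_out, c_in, k)),
       b = numeric(c_out))
}

.init_dense <- function(n_out, n_in) {
  a <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_out * n_in, -a, a), n_out, n_in),
       b = numeric(n_out))
}

.init_se <- function(C, r) {
  cr <- C %/% r
  w1 <- .init_dense(cr, C)
  w2 <- .init_dense(C, cr)
  list(W1 = w1$W, b1 = w1$b, W2 = w2$W, b2 = w2$b)
}

#' Initialize network parameters
#'
#' Uniform fan-in scaling `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` for every
#' weight tensor, zero biases; fully deterministic from `seed`, which is
#' stored with the parameters.
#'
#' @param cfg a [smafnet_config()].
#' @param seed integer RNG seed.
#' @return object of class `smafnet_params`: list with `weights` (nested
#'   list of arrays keyed by module path) and `seed`.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "smafnet_config"))
  sh <- smafnet_shapes(cfg)
  C <- cfg$msfem$channels
  n <- length(cfg$msfem$kernel_sizes)
  H <- .csafm_hidden(cfg)
  wt <- with_seed(seed, {
    w <- list()
    w$spm <- list(conv = .init_conv(cfg$spm$out_channels, 1L,
                                    cfg$spm$kernel_size))
    w$msfem <- lapply(seq_len(n), function(b) {
      k <- cfg$msfem$kernel_sizes[b]
      lapply(seq_len(cfg$msfem$depth), function(l) {
        c_in <- if (l == 1L) cfg$spm$out_channels else C
        list(conv = .init_conv(C, c_in, k),
             se = .init_se(C, cfg$msfem$se_reduction))
      })
    })
    w$csafm <- lapply(seq_len(n), function(r) {
      partners <- setdiff(seq_len(n), r)
      out <- lapply(partners, function(j) {
        list(conv1 = .init_conv(H, 2L * C, cfg$csafm$kernel1),
             conv2 = .init_conv(C, H, cfg$csafm$kernel2))
      })
      names(out) <- vapply(partners, function(j) paste0("j", j), character(1))
      out
    })
    w$head <- list(fc1 = .init_dense(cfg$head_hidden, sh$flat_width),
                   fc2 = .init_dense(1L, cfg$head_hidden))
    w
  })
  structure(list(weights = wt, seed = as.integer(seed)),
            class = "smafnet_params")
}

# ---- forward / backward --------------------------------------------------

.concat_channels <- function(a, b) {
  da <- dim(a)
  z <- array(0, c(da[1L] + dim(b)[1L], da[2L], da[3L]))
  z[seq_len(da[1L]), , ] <- a
  z[(da[1L] + 1L):dim(z)[1L], , ] <- b
  z
}

# Full forward pass on a 1 x L x B array; returns probabilities and, when
# keep_cache, everything the backward pass needs.
.smafnet_forward_arr <- function(xarr, cfg, wt, keep_cache = FALSE) {
  n <- length(cfg$msfem$kernel_sizes)
  d <- cfg$msfem$depth
  bsz <- dim(xarr)[3L]

  c1 <- .conv1d_forward(xarr, wt$spm$conv$W, wt$spm$conv$b, pad = 0L)
  p1 <- .maxpool_forward(c1$out, cfg$spm$pool_size, cfg$spm$pool_stride)
  h0 <- p1$out

  feats <- vector("list", n)
  branch_caches <- vector("list", n)
  for (b in seq_len(n)) {
    k <- cfg$msfem$kernel_sizes[b]
    pad <- (k - 1L) %/% 2L
    h <- h0
    fcs <- vector("list", d)
    for (l in seq_len(d)) {
      w <- wt$msfem[[b]][[l]]
      cv <- .conv1d_forward(h, w$conv$W, w$conv$b, pad = pad)
      rl <- .relu_forward(cv$out)
      se <- .se_forward(rl$out, w$se$W1, w$se$b1, w$se$W2, w$se$b2)
      pl <- .maxpool_forward(se$out, cfg$msfem$pool_size,
                             cfg$msfem$pool_stride)
      fcs[[l]] <- list(conv = cv$cache, relu = rl$cache, se = se$cache,
                       pool = pl$cache)
      h <- pl$out
    }
    feats[[b]] <- h
    branch_caches[[b]] <- fcs
  }

  pad1 <- (cfg$csafm$kernel1 - 1L) %/% 2L
  pad2 <- (cfg$csafm$kernel2 - 1L) %/% 2L
  frs <- vector("list", n)
  cs_caches <- vector("list", n)
  for (r in seq_len(n)) {
    fr <- feats[[r]]
    pc <- list()
    for (j in setdiff(seq_len(n), r)) {
      wp <- wt$csafm[[r]][[paste0("j", j)]]
      z <- .concat_channels(feats[[r]], feats[[j]])
      cv1 <- .conv1d_forward(z, wp$conv1$W, wp$conv1$b, pad = pad1)
      rl <- .relu_forward(cv1$out)
      cv2 <- .conv1d_forward(rl$out, wp$conv2$W, wp$conv2$b, pad = pad2)
      a <- .sigmoid(cv2$out)
      fr <- fr + a * feats[[j]]
      pc[[paste0("j", j)]] <- list(conv1 = cv1$cache, relu = rl$cache,
                                   conv2 = cv2$cache, a = a)
    }
    frs[[r]] <- fr
    cs_caches[[r]] <- pc
  }

  cc <- dim(feats[[1L]])[1L]
  tc <- dim(feats[[1L]])[2L]
  flat <- do.call(rbind, lapply(frs, function(f) {
    dim(f) <- c(cc * tc, bsz)
    f
  }))
  f1 <- .dense_forward(flat, wt$head$fc1$W, wt$head$fc1$b)
  r1 <- .relu_forward(f1$out)
  f2 <- .dense_forward(r1$out, wt$head$fc2$W, wt$head$fc2$b)
  prob <- as.numeric(.sigmoid(f2$out))

  cache <- if (keep_cache) {
    list(spm = list(conv = c1$cache, pool = p1$cache),
         branches = branch_caches, feats = feats, csafm = cs_caches,
         head = list(f1 = f1$cache, r1 = r1$cache, f2 = f2$cache),
         dims = list(n = n, d = d, cc = cc, tc = tc, bsz = bsz))
  } else NULL
  list(prob = prob, cache = cache)
}

# Backward pass from d(loss)/d(logit) (length-B vector). Returns gradients
# in a tree parallel to the weight tree.
.smafnet_backward_arr <- function(dlogit, cache, cfg, wt) {
  dm <- cache$dims
  n <- dm$n; d <- dm$d; cc <- dm$cc; tc <- dm$tc; bsz <- dm$bsz
  g <- list()

  d2 <- .dense_backward(matrix(dlogit, 1L, bsz), cache$head$f2)
  dr1 <- .relu_backward(d2$dx, cache$head$r1)
  d1 <- .dense_backward(dr1, cache$head$f1)
  g$head <- list(fc1 = list(W = d1$dW, b = d1$db),
                 fc2 = list(W = d2$dW, b = d2$db))
  dflat <- d1$dx

  dfeats <- lapply(seq_len(n), function(i) array(0, c(cc, tc, bsz)))
  g$csafm <- vector("list", n)
  for (r in seq_len(n)) {
    rows <- ((r - 1L) * cc * tc + 1L):(r * cc * tc)
    dfr <- array(dflat[rows, , drop = FALSE], c(cc, tc, bsz))
    dfeats[[r]] <- dfeats[[r]] + dfr
    gpairs <- list()
    for (j in setdiff(seq_len(n), r)) {
      key <- paste0("j", j)
      pc <- cache$csafm[[r]][[key]]
      a <- pc$a
      xj <- cache$feats[[j]]
      dfeats[[j]] <- dfeats[[j]] + dfr * a
      dz2 <- (dfr * xj) * a * (1 - a)
      b2 <- .conv1d_backward(dz2, pc$conv2)
      dpre1 <- .relu_backward(b2$dx, pc$relu)
      b1 <- .conv1d_backward(dpre1, pc$conv1)
      dz <- b1$dx
      dfeats[[r]] <- dfeats[[r]] + dz[seq_len(cc), , , drop = FALSE]
      dfeats[[j]] <- dfeats[[j]] + dz[(cc + 1L):(2L * cc), , , drop = FALSE]
      gpairs[[key]] <- list(conv1 = list(W = b1$dW, b = b1$db),
                            conv2 = list(W = b2$dW, b = b2$db))
    }
    g$csafm[[r]] <- gpairs
  }

  dh0 <- NULL
  g$msfem <- vector("list", n)
  for (b in seq_len(n)) {
    dh <- dfeats[[b]]
    gblocks <- vector("list", d)
    for (l in rev(seq_len(d))) {
      fc <- cache$branches[[b]][[l]]
      dse_out <- .maxpool_backward(dh, fc$pool)
      seb <- .se_backward(dse_out, fc$se)
      drelu <- .relu_backward(seb$dx, fc$relu)
      cvb <- .conv1d_backward(drelu, fc$conv)
      gblocks[[l]] <- list(conv = list(W = cvb$dW, b = cvb$db),
                           se = list(W1 = seb$dW1, b1 = seb$db1,
                                     W2 = seb$dW2, b2 = seb$db2))
      dh <- cvb$dx
    }
    g$msfem[[b]] <- gblocks
    dh0 <- if (is.null(dh0)) dh else dh0 + dh
  }

  dspm <- .maxpool_backward(dh0, cache$spm$pool)
  spb <- .conv1d_backward(dspm, cache$spm$conv)
  g$spm <- list(conv = list(W = spb$dW, b = spb$db))

  # order the gradient tree exactly like the weight tree
  g[names(wt)]
}

# ---- exported building-block operations ----------------------------------

#' One feature extraction block
#'
#' Same-padded convolution at the block's kernel size, ReLU,
#' squeeze-and-excitation recalibration, then max-pooling (the temporal
#' length halves, rounding down, with the default 2/2 pooling).
#'
#' @param x `C_in x T` matrix (or `C x T x B` array).
#' @param cfg list with `kernel_size` (odd) and optionally `pool_size`,
#'   `pool_stride` (default 2/2).
#' @param params list with `conv = list(W, b)` and
#'   `se = list(W1, b1, W2, b2)`.
#' @return pooled feature map, same container type as `x`.
#' @export
feb_forward <- function(x, cfg, params) {
  xarr <- .as_cmap(x)
  k <- dim(params$conv$W)[3L]
  if (!is.null(cfg$kernel_size) && cfg$kernel_size != k) {
    stop("cfg$kernel_size disagrees with the kernel bank", call. = FALSE)
  }
  if (k %% 2L == 0L) stop("FEB kernels must be odd for same-padding", call. = FALSE)
  ps <- if (is.null(cfg$pool_size)) 2L else cfg$pool_size
  st <- if (is.null(cfg$pool_stride)) ps else cfg$pool_stride
  cv <- .conv1d_forward(xarr, params$conv$W, params$conv$b,
                        pad = (k - 1L) %/% 2L)
  rl <- .relu_forward(cv$out)
  se <- .se_forward(rl$out, params$se$W1, params$se$b1,
                    params$se$W2, params$se$b2)
  out <- .maxpool_forward(se$out, ps, st)$out
  if (is.matrix(x) || is.null(dim(x))) matrix(out, dim(out)[1L], dim(out)[2L])
  else out
}

#' Multi-scale feature extraction
#'
#' Branch `b` applies `depth` sequential feature extraction blocks, all at
#' `kernel_sizes[b]`. Same-padding plus identical pooling guarantees every
#' branch output shares one `C x T'` shape, which is what makes cross-scale
#' fusion possible.
#'
#' @param x input feature map (`C x T` matrix or `C x T x B` array),
#'   typically the SPM output.
#' @param cfg a [msfem_config()].
#' @param params list over branches, each a list over depth of FEB
#'   parameter lists (as in the `msfem` slot of [init_model()] weights).
#' @return list of `length(cfg$kernel_sizes)` feature maps.
#' @export
msfem_forward <- function(x, cfg, params) {
  stopifnot(inherits(cfg, "msfem_config"))
  lapply(seq_along(cfg$kernel_sizes), function(b) {
    h <- x
    for (l in seq_len(cfg$depth)) {
      h <- feb_forward(h, list(kernel_size = cfg$kernel_sizes[b],
                               pool_size = cfg$pool_size,
                               pool_stride = cfg$pool_stride),
                       params[[b]][[l]])
    }
    h
  })
}

#' Cross-scale attention fusion onto one reference scale
#'
#' For every partner scale `j != r`: concatenate `(X_r, X_j)` along
#' channels, pass through conv1 + ReLU + conv2 + sigmoid to obtain
#' attention weights `a_j` in (0, 1) shaped like `X_j`, recalibrate
#' `X_j` element-wise, and add all recalibrated partners onto `X_r`.
#' With a single scale the fused feature is `X_r` itself.
#'
#' @param features list of feature maps sharing one `C x T'` shape.
#' @param r reference scale index.
#' @param params named list with one element `j<index>` per partner, each
#'   holding `conv1 = list(W, b)` and `conv2 = list(W, b)`.
#' @return fused feature map `F_r`, same shape as `features[[r]]`.
#' @export
csafm_fuse <- function(features, r, params) {
  n <- length(features)
  stopifnot(r >= 1L, r <= n)
  arrs <- lapply(features, .as_cmap)
  shp <- dim(arrs[[1L]])
  for (f in arrs) {
    if (!identical(dim(f), shp)) stop("all scales must share one shape",
                                      call. = FALSE)
  }
  fr <- arrs[[r]]
  for (j in setdiff(seq_len(n), r)) {
    wp <- params[[paste0("j", j)]]
    if (is.null(wp)) stop("missing fusion parameters for partner ", j,
                          call. = FALSE)
    k1 <- dim(wp$conv1$W)[3L]
    k2 <- dim(wp$conv2$W)[3L]
    z <- .concat_channels(arrs[[r]], arrs[[j]])
    h <- .conv1d_forward(z, wp$conv1$W, wp$conv1$b,
                         pad = (k1 - 1L) %/% 2L)$out
    h <- pmax(h, 0)
    a <- .sigmoid(.conv1d_forward(h, wp$conv2$W, wp$conv2$b,
                                  pad = (k2 - 1L) %/% 2L)$out)
    fr <- fr + a * arrs[[j]]
  }
  if (is.matrix(features[[r]])) matrix(fr, shp[1L], shp[2L]) else fr
}

#' Forward pass: spectra to adulteration probabilities
#'
#' @param x spectra: a [spectra_set()], a numeric `N x L` matrix (rows =
#'   samples) or a length-`L` vector.
#' @param cfg a [smafnet_config()] with `input_length = L`.
#' @param params a `smafnet_params` object from [init_model()] (or its
#'   weight tree).
#' @return numeric vector of `N` probabilities, each strictly in (0, 1).
#' @export
smafnet_forward <- function(x, cfg, params) {
  stopifnot(inherits(cfg, "smafnet_config"))
  X <- if (inherits(x, "spectra_set")) x$absorbance
       else if (is.null(dim(x))) matrix(x, nrow = 1L)
       else as.matrix(x)
  if (ncol(X) != cfg$input_length) {
    stop("spectra have ", ncol(X), " points but the model expects ",
         cfg$input_length, call. = FALSE)
  }
  wt <- .unwrap_weights(params)
  xarr <- array(t(X), c(1L, ncol(X), nrow(X)))
  .smafnet_forward_arr(xarr, cfg, wt, keep_cache = FALSE)$prob
}
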