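# Independent brute-force oracles and small fixtures used across the
# suite. Everything here is deliberately written with explicit loops so
# it shares no code path with the implementation it checks.

# Valid cross-correlation, triple loop over (output channel, position, tap).
oracle_conv1d_valid <- function(x, W, bias = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(W))) W <- array(W, c(1, 1, length(W)))
  c_out <- dim(W)[1]; c_in <- dim(W)[2]; k <- dim(W)[3]
  t_out <- ncol(x) - k + 1
  y <- matrix(0, c_out, t_out)
  for (o in seq_len(c_out)) {
    for (t in seq_len(t_out)) {
      acc <- 0
      for (ci in seq_len(c_in)) {
        for (i in seq_len(k)) {
          acc <- acc + x[ci, t + i - 1] * W[o, ci, i]
        }
      }
      y[o, t] <- acc + if (is.null(bias)) 0 else bias[o]
    }
  }
  y
}

# Squeeze-and-excitation in three explicit stages.
oracle_se <- function(x, W1, b1, W2, b2) {
  C <- nrow(x); T <- ncol(x)
  s <- numeric(C)
  for (c in seq_len(C)) s[c] <- mean(x[c, ])
  z1 <- as.numeric(W1 %*% s + b1)
  a1 <- ifelse(z1 > 0, z1, 0)
  z2 <- as.numeric(W2 %*% a1 + b2)
  g <- 1 / (1 + exp(-z2))
  y <- x
  for (c in seq_len(C)) y[c, ] <- x[c, ] * g[c]
  y
}

# SPXY greedy max-min selection with explicit loops.
oracle_spxy <- function(X, y, ratio) {
  n <- nrow(X)
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    dy[i, j] <- abs(y[i] - y[j])
  }
  d <- matrix(0, n, n)
  if (max(dx) > 0) d <- d + dx / max(dx)
  if (max(dy) > 0) d <- d + dy / max(dy)
  n_cal <- ceiling(ratio * n)
  best <- -1; bi <- bj <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > best) { best <- d[i, j]; bi <- i; bj <- j }
  }
  sel <- c(bi, bj)
  if (n_cal <= 1) sel <- bi
  while (length(sel) < n_cal) {
    cand_best <- -1; cand <- 0
    for (i in seq_len(n)) {
      if (i %in% sel) next
      mind <- Inf
      for (s in sel) mind <- min(mind, d[i, s])
      if (mind > cand_best) { cand_best <- mind; cand <- i }
    }
    sel <- c(sel, cand)
  }
  list(calibration_idx = sel, validation_idx = setdiff(seq_len(n), sel))
}

# Per-sample confusion tally.
oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Small architecture for fast structural / gradient tests.
tiny_config <- function(input_length = 32, kernel_sizes = c(1, 3), depth = 2,
                        channels = 4, head_hidden = 6) {
  smafnet_config(
    input_length = input_length,
    spm = spm_config(kernel_size = 4, out_channels = channels),
    msfem = msfem_config(kernel_sizes = kernel_sizes, depth = depth,
                         channels = channels, se_reduction = 2),
    csafm = csafm_config(),
    head_hidden = head_hidden)
}

# Small labelled spectra_set with arbitrary feature content.
toy_set <- function(X, labels, wavelengths = NULL) {
  n <- nrow(X)
  if (is.null(wavelengths)) wavelengths <- seq(1000, by = 3, length.out = ncol(X))
  colorant <- ifelse(labels == 1, "sunset_yellow", "none")
  conc <- ifelse(labels == 1, 0.3, 0)
  spectra_set(wavelengths, X, labels, colorant, conc,
              sprintf("s%03d", seq_len(n)))
}

# Zero-signal design: colorant present in the bookkeeping but with no
# spectral consequence, balanced classes.
null_design <- function(seed = 1L) {
  synthetic_design(
    n_pure = 72, n_per_colorant = 73, colorants = "sunset_yellow",
    global_effect = 0,
    colorant_bands = list(
      sunset_yellow = c(center = 1005, width = 18, amplitude = 0),
      tartrazine    = c(center = 1210, width = 16, amplitude = 0),
      ponceau_4r    = c(center = 1555, width = 20, amplitude = 0)),
    seed = seed)
}
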