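# Optimization: binary cross-entropy objective minimized with Adam
# (lr 0.001, beta1 0.9, beta2 0.999, epsilon 1e-8 by default), fixed-seed
# shuffling, plus the kernel/scale/depth architecture sweep.

#' Training configuration
#'
#' Adam hyperparameters follow the published settings (initial learning
#' rate 0.001, beta1 0.9, beta2 0.999, epsilon 1e-8, constant rate).
#' Epoch count and batch size are free choices sized for ~100-sample
#' calibration sets; 150 epochs comfortably passes the optimization
#' plateau observed on data of this scale.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam settings.
#' @param epochs number of passes over the calibration set (default 150).
#' @param batch_size mini-batch size (default 16).
#' @param seed RNG seed controlling initialization and shuffling.
#' @param early_stop optional integer patience on validation accuracy;
#'   `NULL` (default) disables early stopping.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, epochs = 150, batch_size = 16,
                         seed = 1L, early_stop = NULL) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 early_stop = early_stop),
            class = "train_config")
}

.bce_loss <- function(prob, y) {
  eps <- 1e-12
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the network
#'
#' Minimizes binary cross-entropy with Adam. Deterministic for a given
#' `tcfg$seed`: initialization, shuffling, and hence the final weights are
#' bit-reproducible on one machine.
#'
#' @param cfg a [smafnet_config()]; `input_length` must match the data.
#' @param tcfg a [train_config()].
#' @param train calibration [spectra_set()]; must contain both classes.
#' @param val optional validation `spectra_set`; when given, per-epoch
#'   validation accuracy and F1 are recorded in the history.
#' @return an object of class `smafnet_fit`: list with `config`, `params`
#'   (a `smafnet_params`), `train_config`, and `history` (a data.frame
#'   with one row per epoch).
#' @export
train_model <- function(cfg, tcfg, train, val = NULL) {
  stopifnot(inherits(cfg, "smafnet_config"), inherits(tcfg, "train_config"),
            inherits(train, "spectra_set"))
  if (length(unique(train$labels)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (ncol(train$absorbance) != cfg$input_length) {
    stop("training spectra length does not match cfg$input_length",
         call. = FALSE)
  }
  X <- train$absorbance
  y <- as.numeric(train$labels)
  n <- nrow(X)

  params <- init_model(cfg, seed = tcfg$seed)
  wt <- params$weights
  m <- .tree_map(function(w) w * 0, wt)
  v <- m
  step <- 0L

  n_epochs <- tcfg$epochs
  hist_loss <- numeric(n_epochs)
  hist_acc <- rep(NA_real_, n_epochs)
  hist_f1 <- rep(NA_real_, n_epochs)

  with_seed(tcfg$seed, {
    for (ep in seq_len(n_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = tcfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + tcfg$batch_size - 1L, n)]
        bsz <- length(idx)
        xarr <- array(t(X[idx, , drop = FALSE]), c(1L, ncol(X), bsz))
        fwd <- .smafnet_forward_arr(xarr, cfg, wt, keep_cache = TRUE)
        yb <- y[idx]
        ep_loss <- ep_loss + .bce_loss(fwd$prob, yb) * bsz
        dlogit <- (fwd$prob - yb) / bsz
        grads <- .smafnet_backward_arr(dlogit, fwd$cache, cfg, wt)
        step <- step + 1L
        m <- .tree_map(function(mm, gg) tcfg$beta1 * mm + (1 - tcfg$beta1) * gg,
                       m, grads)
        v <- .tree_map(function(vv, gg) tcfg$beta2 * vv + (1 - tcfg$beta2) * gg^2,
                       v, grads)
        bc1 <- 1 - tcfg$beta1^step
        bc2 <- 1 - tcfg$beta2^step
        lr <- tcfg$learning_rate
        wt <- .tree_map(function(ww, mm, vv) {
          ww - lr * (mm / bc1) / (sqrt(vv / bc2) + tcfg$epsilon)
        }, wt, m, v)
      }
      hist_loss[ep] <- ep_loss / n
      if (!is.null(val)) {
        pv <- .smafnet_forward_arr(
          array(t(val$absorbance), c(1L, ncol(val$absorbance),
                                     nrow(val$absorbance))),
          cfg, wt, keep_cache = FALSE)$prob
        mr <- compute_metrics(confusion_matrix(val$labels,
                                               as.integer(pv >= 0.5)))
        hist_acc[ep] <- mr$ACC
        hist_f1[ep] <- mr$F1
      }
    }
  })

  params$weights <- wt
  history <- data.frame(epoch = seq_len(n_epochs), loss = hist_loss,
                        val_acc = hist_acc, val_f1 = hist_f1)
  structure(list(config = cfg, params = params, train_config = tcfg,
                 history = history),
            class = "smafnet_fit")
}

#' @export
print.smafnet_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<smafnet_fit> %d epochs, final training loss %.4f\n",
              nrow(x$history), last$loss))
  if (!is.na(last$val_acc)) {
    cat(sprintf("  final validation ACC %.2f%%, F1 %.4f\n",
                last$val_acc, last$val_f1))
  }
  invisible(x)
}

#' Predict adulteration from a fitted model
#'
#' @param object a `smafnet_fit`.
#' @param newdata a [spectra_set()] or `N x L` matrix.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 labels at the
#'   0.5 decision threshold (adulterated = positive class).
#' @param ... ignored.
#' @export
predict.smafnet_fit <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  p <- smafnet_forward(newdata, object$config, object$params)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Evaluate a fitted model on a labelled set
#'
#' @param fit a `smafnet_fit`.
#' @param set a [spectra_set()].
#' @return list with `confusion` ([confusion_matrix()]) and `metrics`
#'   ([compute_metrics()] report).
#' @export
evaluate_model <- function(fit, set) {
  stopifnot(inherits(fit, "smafnet_fit"), inherits(set, "spectra_set"))
  pred <- predict(fit, set, type = "class")
  cm <- confusion_matrix(set$labels, pred)
  list(confusion = cm, metrics = compute_metrics(cm))
}

#' Architecture sweep over a configuration grid
#'
#' Trains every configuration with one common training configuration
#' (identical seed, so rows are comparable) and reports validation accuracy
#' and F1, sorted by descending ACC then F1 — the layout used when
#' selecting kernel sizes, scale count and depth.
#'
#' @param grid non-empty list of [smafnet_config()] objects.
#' @param tcfg a [train_config()].
#' @param train,val calibration and validation [spectra_set()]s.
#' @return data.frame with columns `kernels`, `n_scales`, `depth`, `ACC`,
#'   `F1`; the matching configs (in sorted order) are in
#'   `attr(, "configs")`.
#' @export
sweep_configs <- function(grid, tcfg, train, val) {
  if (!is.list(grid) || length(grid) < 1L) {
    stop("grid must be a non-empty list of configurations", call. = FALSE)
  }
  rows <- lapply(grid, function(cfg) {
    fit <- train_model(cfg, tcfg, train, val)
    ev <- evaluate_model(fit, val)
    data.frame(
      kernels = paste(cfg$msfem$kernel_sizes, collapse = ","),
      n_scales = length(cfg$msfem$kernel_sizes),
      depth = cfg$msfem$depth,
      ACC = ev$metrics$ACC,
      F1 = ev$metrics$F1,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$ACC, -out$F1)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "configs") <- grid[ord]
  out
}

#' Save / load a model checkpoint
#'
#' One file holding the architecture config, the learned parameters
#' (including the initialization seed), the training configuration and the
#' training history.
#'
#' @param fit a `smafnet_fit`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `smafnet_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "smafnet_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "smafnet_fit")) stop("not a model checkpoint: ", path,
                                          call. = FALSE)
  fit
}
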