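# Architecture: shape soundness, fusion identities, initialization,
# parameter accounting.

test_that("configurations validate their invariants", {
  expect_error(msfem_config(kernel_sizes = c(2, 4)), "odd")
  expect_error(msfem_config(kernel_sizes = c(1, 3, 5, 7)), "1 and 3")
  expect_error(msfem_config(depth = 4), "depth")
  expect_error(msfem_config(channels = 30, se_reduction = 8), "divisible")
  expect_error(smafnet_config(input_length = 10,
                              spm = spm_config(kernel_size = 16)),
               "shorter than the SPM kernel")
  sh <- smafnet_shapes(smafnet_config())
  expect_equal(sh$t_spm_conv, 252L)   # 267 - 16 + 1
  expect_equal(sh$t_spm, 126L)
  expect_equal(sh$t_final, 31L)       # floor(floor(126/2)/2)
  expect_equal(sh$flat_width, 3L * 64L * 31L)
})

test_that("FEB halves the temporal length and reduces to pooling for unit settings", {
  cfgf <- list(kernel_size = 1, pool_size = 2, pool_stride = 2)
  C <- 3; T <- 8
  # identity convolution, SE gates forced to 1 via huge excitation bias
  params <- list(conv = list(W = array(diag(C), c(C, C, 1)), b = rep(0, C)),
                 se = list(W1 = matrix(0, 1, C), b1 = 0,
                           W2 = matrix(0, C, 1), b2 = rep(50, C)))
  x <- matrix(abs(rnorm(C * T)) + 0.1, C, T)
  out <- feb_forward(x, cfgf, params)
  pooled <- smafnet:::.maxpool_forward(array(x, c(C, T, 1)), 2, 2)$out
  expect_equal(out, matrix(pooled, C, T / 2), tolerance = 1e-10)
  expect_equal(ncol(out), T %/% 2L)
})

test_that("parallel branches share one output shape and permute with kernels", {
  cfg <- msfem_config(kernel_sizes = c(1, 5, 9), depth = 2, channels = 8,
                      se_reduction = 2)
  full <- smafnet_config(input_length = 267,
                         spm = spm_config(out_channels = 8),
                         msfem = cfg, head_hidden = 8)
  pm <- init_model(full, seed = 2)
  x <- matrix(rnorm(8 * 126, 0.5, 0.2), 8, 126)
  feats <- msfem_forward(x, cfg, pm$weights$msfem)
  expect_length(feats, 3L)
  for (f in feats) expect_equal(dim(f), c(8L, 31L))

  # permuting the branch order (with matched parameters) permutes outputs
  perm <- c(3, 1, 2)
  cfg_p <- msfem_config(kernel_sizes = cfg$kernel_sizes[perm], depth = 2,
                        channels = 8, se_reduction = 2)
  feats_p <- msfem_forward(x, cfg_p, pm$weights$msfem[perm])
  expect_equal(feats_p, feats[perm])
})

test_that("cross-scale fusion honours its identities and attention range", {
  set.seed(33)
  C <- 4; Tp <- 5
  x1 <- matrix(rnorm(C * Tp), C, Tp)
  x2 <- matrix(rnorm(C * Tp), C, Tp)
  mk_pair <- function() list(
    conv1 = list(W = array(rnorm(C * 2 * C, 0, 0.4), c(C, 2 * C, 1)),
                 b = rnorm(C, 0, 0.1)),
    conv2 = list(W = array(rnorm(C * C, 0, 0.4), c(C, C, 1)),
                 b = rnorm(C, 0, 0.1)))
  # single scale: fused feature is the reference itself
  expect_identical(csafm_fuse(list(x1), 1, list()), x1)
  # zero partners contribute nothing
  params <- list(j2 = mk_pair())
  expect_equal(csafm_fuse(list(x1, matrix(0, C, Tp)), 1, params), x1)
  # hand-computed two-scale trace, C = 1, T' = 2
  w1 <- array(c(0.5, -0.3), c(1, 2, 1)); b1 <- 0.1
  w2 <- array(0.8, c(1, 1, 1)); b2 <- -0.2
  xa <- matrix(c(1, 2), 1); xb <- matrix(c(3, -1), 1)
  z <- rbind(xa, xb)
  pre1 <- as.numeric(w1[1, 1, 1] * z[1, ] + w1[1, 2, 1] * z[2, ] + b1)
  h <- pmax(pre1, 0)
  a <- 1 / (1 + exp(-(0.8 * h - 0.2)))
  want <- xa + a * xb
  got <- csafm_fuse(list(xa, xb), 1,
                    list(j2 = list(conv1 = list(W = w1, b = b1),
                                   conv2 = list(W = w2, b = b2))))
  expect_equal(got, want, tolerance = 1e-12)
  # attention strictly inside (0,1): fused deviation bounded by |partner|
  dev <- csafm_fuse(list(x1, x2), 1, params) - x1
  expect_true(all(abs(dev) < abs(x2) + 1e-12))
  expect_true(all(dev != 0))
  expect_error(csafm_fuse(list(x1, x2[, 1:3]), 1, params), "one shape")
})

test_that("forward pass stays in (0,1) for representative scale/depth settings", {
  kernel_sets <- list(5, c(1, 9), c(1, 5, 9))
  x <- matrix(rnorm(2 * 267, 0.5, 0.2), 2, 267)
  for (ks in kernel_sets) {
    for (d in c(1, 3)) {
      cfg <- smafnet_config(
        msfem = msfem_config(kernel_sizes = ks, depth = d, channels = 16,
                             se_reduction = 4),
        spm = spm_config(out_channels = 16), head_hidden = 16)
      pm <- init_model(cfg, seed = 1)
      p <- smafnet_forward(x, cfg, pm)
      expect_length(p, 2L)
      expect_true(all(p > 0 & p < 1),
                  label = sprintf("probabilities for kernels {%s}, d=%d",
                                  paste(ks, collapse = ","), d))
    }
  }
})

test_that("identical rows give identical outputs and L mismatches error", {
  cfg <- tiny_config()
  pm <- init_model(cfg, seed = 6)
  row <- rnorm(32, 0.5, 0.2)
  p <- smafnet_forward(rbind(row, row, row), cfg, pm)
  expect_equal(p[1], p[2])
  expect_equal(p[2], p[3])
  expect_error(smafnet_forward(matrix(rnorm(10), 1), cfg, pm), "expects")
})

test_that("initialization is seed-deterministic and counts parameters in closed form", {
  cfg <- smafnet_config()
  a <- init_model(cfg, seed = 5)
  b <- init_model(cfg, seed = 5)
  expect_identical(a$weights, b$weights)
  expect_equal(a$seed, 5L)
  c2 <- init_model(cfg, seed = 6)
  expect_false(identical(a$weights, c2$weights))

  # independent shape accounting
  L <- 267; k_spm <- 16; C0 <- 64; C <- 64; r <- 8
  n <- 3; d <- 2; H <- 64; hidden <- 128
  t_final <- ((L - k_spm + 1) %/% 2) %/% 2 %/% 2
  spm_n <- C0 * 1 * k_spm + C0
  feb_n <- function(c_in, k) (C * c_in * k + C) +
    ((C %/% r) * C + C %/% r) + (C * (C %/% r) + C)
  msfem_n <- 0
  for (ks in c(1, 5, 9)) {
    msfem_n <- msfem_n + feb_n(C0, ks) + (d - 1) * feb_n(C, ks)
  }
  pair_n <- (H * 2 * C * 1 + H) + (C * H * 1 + C)
  csafm_n <- n * (n - 1) * pair_n
  D <- n * C * t_final
  head_n <- (hidden * D + hidden) + (1 * hidden + 1)
  expect_equal(n_parameters(a), spm_n + msfem_n + csafm_n + head_n)
})
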