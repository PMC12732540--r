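# Synthetic spectra generator: band structure, adulteration effect,
# dataset assembly, reproducibility.

test_that("tea baseline reduces to the linear part when bands vanish", {
  d0 <- synthetic_design(band_amplitudes = c(0, 0, 0, 0),
                         baseline_offset = 0, baseline_slope = 0)
  wl <- d0$wavelengths
  expect_equal(tea_baseline(wl, d0), rep(0, length(wl)))

  # single band: value at the center is baseline + amplitude
  d1 <- synthetic_design(band_centers = 1200, band_widths = 30,
                         band_amplitudes = 0.4, baseline_offset = 0.1,
                         baseline_slope = 0)
  curve <- tea_baseline(d1$wavelengths, d1)
  expect_equal(curve[which(d1$wavelengths == 1200)], 0.5)
})

test_that("default baseline peaks in the strong 1430-1500 nm window", {
  d <- synthetic_design()
  wl <- d$wavelengths
  curve <- tea_baseline(wl, d)
  peak <- wl[which.max(curve)]
  expect_gte(peak, 1430)
  expect_lte(peak, 1500)
  # strong band dominates the weak 1170-1220 nm band
  expect_gt(max(curve[wl >= 1430 & wl <= 1500]),
            max(curve[wl >= 1170 & wl <= 1220]))
})

test_that("adulteration lowers absorbance, scales linearly, validates inputs", {
  d <- synthetic_design()
  base <- tea_baseline(d$wavelengths, d)
  # zero effect + zero colorant band = identity
  d0 <- null_design()
  base0 <- tea_baseline(d0$wavelengths, d0)
  expect_identical(apply_adulteration(base0, "sunset_yellow", 0.3, d0), base0)
  # linearity of the deviation in concentration
  dev1 <- apply_adulteration(base, "tartrazine", 0.1, d) - base
  dev2 <- apply_adulteration(base, "tartrazine", 0.2, d) - base
  expect_equal(dev2, 2 * dev1, tolerance = 1e-12)
  # mean absorbance strictly decreases at the top dose
  adult <- apply_adulteration(base, "sunset_yellow", 0.5, d)
  expect_lt(mean(adult), mean(base))
  # suppression wherever the colorant band is negligible
  far <- abs(d$wavelengths - d$colorant_bands$sunset_yellow[["center"]]) >
    5 * d$colorant_bands$sunset_yellow[["width"]]
  expect_true(all(adult[far] <= base[far]))
  expect_error(apply_adulteration(base, "sunset_yellow", 0, d), "positive")
  expect_error(apply_adulteration(base, "sunset_yellow", -1, d), "positive")
  expect_error(apply_adulteration(base, "none", 0.3, d), "unknown colorant")
})

test_that("default design reproduces the study-scale inventory", {
  set <- generate_dataset(synthetic_design())
  expect_equal(n_samples(set), 345L)
  expect_equal(sum(set$labels == 0L), 45L)
  expect_equal(unname(table(set$colorant)[c("sunset_yellow", "tartrazine",
                                            "ponceau_4r")]),
               rep(100L, 3), ignore_attr = TRUE)
  # concentrations cycle the 9-level grid, surplus at the low levels
  cc <- table(set$concentration[set$colorant == "sunset_yellow"])
  expect_equal(length(cc), 9L)
  expect_true(all(cc %in% c(11L, 12L)))
  expect_equal(unname(cc[1]), 12L)
  # per-sample ids unique and shaped as expected
  expect_true(all(grepl("^(pure|sunset_yellow|tartrazine|ponceau_4r)_\\d{3}$",
                        set$sample_id)))
})

test_that("degenerate generator settings are handled per contract", {
  expect_error(generate_dataset(
    synthetic_design(n_pure = 0, n_per_colorant = 3,
                     colorants = character(0))), "at least one colorant")
  one <- generate_dataset(synthetic_design(n_pure = 0, n_per_colorant = 1,
                                           colorants = "ponceau_4r"))
  expect_equal(n_samples(one), 1L)
  expect_equal(one$labels, 1L)
  # noise-free, effect-free: every row equals the pure baseline
  quiet <- null_design()
  quiet$noise_sd <- 0; quiet$scatter_mult_sd <- 0; quiet$scatter_add_sd <- 0
  setq <- generate_dataset(quiet)
  base <- tea_baseline(quiet$wavelengths, quiet)
  expect_equal(max(abs(sweep(setq$absorbance, 2, base))), 0)
})

test_that("generation is a pure function of the seed", {
  d1 <- synthetic_design(n_pure = 10, n_per_colorant = 12, seed = 5)
  a <- generate_dataset(d1)
  b <- generate_dataset(d1)
  expect_identical(a$absorbance, b$absorbance)
  expect_identical(a$sample_id, b$sample_id)
  d2 <- synthetic_design(n_pure = 10, n_per_colorant = 12, seed = 6)
  c2 <- generate_dataset(d2)
  expect_false(identical(a$absorbance, c2$absorbance))
  expect_identical(a$labels, c2$labels)
  expect_identical(a$colorant, c2$colorant)
})

test_that("mean adulterated spectrum sits below the pure mean away from colorant bands", {
  set <- generate_dataset(synthetic_design(seed = 2))
  wl <- set$wavelengths
  m_pure <- colMeans(set$absorbance[set$labels == 0L, , drop = FALSE])
  m_adult <- colMeans(set$absorbance[set$labels == 1L, , drop = FALSE])
  d <- synthetic_design()
  near_band <- rep(FALSE, length(wl))
  for (b in d$colorant_bands) {
    near_band <- near_band | abs(wl - b[["center"]]) <= 4 * b[["width"]]
  }
  expect_true(all(m_adult[!near_band] <= m_pure[!near_band]))
})

test_that("class-mean separation grows with the global effect size", {
  seps <- vapply(c(0.01, 0.05, 0.10), function(eff) {
    s <- generate_dataset(synthetic_design(n_pure = 30, n_per_colorant = 30,
                                           colorants = "sunset_yellow",
                                           global_effect = eff, seed = 9))
    m0 <- colMeans(s$absorbance[s$labels == 0L, , drop = FALSE])
    m1 <- colMeans(s$absorbance[s$labels == 1L, , drop = FALSE])
    sqrt(sum((m0 - m1)^2))
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})
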