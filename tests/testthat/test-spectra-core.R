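# Spectra containers, CSV round trips, replicate-scan averaging.

test_that("default wavelength grid matches direct enumeration of 900 + 3k <= 1700", {
  ks <- 0:10000
  expected <- sum(900 + 3 * ks <= 1700)
  grid <- default_wavelength_grid()
  expect_length(grid, expected)
  expect_identical(expected, 267L)
  expect_equal(grid[1], 900)
  expect_equal(grid[length(grid)], 1698)
})

test_that("spectra_set enforces its invariants", {
  wl <- c(1000, 1003)
  ab <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  ok <- spectra_set(wl, ab, c(0, 1), c("none", "tartrazine"), c(0, 0.2),
                    c("a", "b"))
  expect_s3_class(ok, "spectra_set")
  expect_equal(n_samples(ok), 2L)
  # empty set
  expect_error(spectra_set(wl, ab[0, , drop = FALSE], integer(0),
                           character(0), numeric(0), character(0)),
               "at least one sample")
  # label / colorant / concentration coupling
  expect_error(spectra_set(wl, ab, c(0, 1), c("none", "none"), c(0, 0.2),
                           c("a", "b")), "coincide")
  expect_error(spectra_set(wl, ab, c(0, 1), c("none", "tartrazine"), c(0, 0),
                           c("a", "b")), "coincide")
  expect_error(spectra_set(wl, ab, c(0, 2), c("none", "tartrazine"),
                           c(0, 0.2), c("a", "b")), "labels")
  expect_error(spectra_set(wl, ab, c(0, 1), c("none", "tartrazine"),
                           c(0, 0.2), c("a", "a")), "unique")
  expect_error(spectra_set(rev(wl), ab, c(0, 1), c("none", "tartrazine"),
                           c(0, 0.2), c("a", "b")), "increasing")
})

test_that("CSV round trip preserves ids, labels, grid exactly and absorbance to 1e-10", {
  design <- synthetic_design(n_pure = 4, n_per_colorant = 5,
                             colorants = c("sunset_yellow", "ponceau_4r"),
                             seed = 7)
  set <- generate_dataset(design)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(set, path)
  back <- read_spectra_csv(path)
  expect_identical(back$sample_id, set$sample_id)
  expect_identical(back$labels, set$labels)
  expect_identical(back$colorant, set$colorant)
  expect_equal(back$wavelengths, set$wavelengths)
  expect_equal(back$concentration, set$concentration, tolerance = 1e-12)
  rel <- abs(back$absorbance - set$absorbance) /
    pmax(abs(set$absorbance), .Machine$double.eps)
  expect_lt(max(rel), 1e-10)
  # single sample keeps one data row + header
  one <- set[1]
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(one, p1)
  expect_length(readLines(p1), 2L)
  expect_equal(n_samples(read_spectra_csv(p1)), 1L)
})

test_that("malformed spectra CSVs are rejected", {
  design <- synthetic_design(n_pure = 2, n_per_colorant = 2,
                             colorants = "tartrazine", seed = 1)
  set <- generate_dataset(design)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(set, path)
  lines <- readLines(path)

  # label outside {0, 1}
  bad <- sub("^(tartrazine_001),1,", "\\1,2,", lines)
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, p2)
  expect_error(read_spectra_csv(p2), "labels")

  # wrong leading header
  bad2 <- lines
  bad2[1] <- sub("^id,label", "sample,label", bad2[1])
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad2, p3)
  expect_error(read_spectra_csv(p3), "must start with")

  # non-monotone wavelength columns
  hdr <- strsplit(lines[1], ",")[[1]]
  tmp <- hdr[5]; hdr[5] <- hdr[6]; hdr[6] <- tmp
  bad3 <- lines
  bad3[1] <- paste(hdr, collapse = ",")
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad3, p4)
  expect_error(read_spectra_csv(p4), "increasing")

  expect_error(read_spectra_csv(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("average_scans is the pointwise mean and permutation invariant", {
  wl <- seq(900, 930, by = 3)
  s1 <- nir_spectrum(wl, seq_along(wl) * 0.1)
  # idempotence on identical replicates
  avg6 <- average_scans(rep(list(s1), 6))
  expect_equal(avg6$absorbance, s1$absorbance)
  # symmetry: a and -a cancel
  s2 <- nir_spectrum(wl, -s1$absorbance)
  expect_equal(average_scans(list(s1, s2))$absorbance, rep(0, length(wl)))
  # permutation invariance
  set.seed(3)
  reps <- lapply(1:5, function(i) nir_spectrum(wl, rnorm(length(wl))))
  perm <- sample(5)
  expect_identical(average_scans(reps)$absorbance,
                   average_scans(reps[perm])$absorbance)
  # mismatched grids rejected
  s3 <- nir_spectrum(wl + 1, s1$absorbance)
  expect_error(average_scans(list(s1, s3)), "identical wavelength grid")
  expect_error(average_scans(list()), "at least one")
})

test_that("averaging six i.i.d.-noise scans shrinks the sd by sqrt(6)", {
  set.seed(11)
  n_pts <- 10000   # Monte-Carlo over wavelengths
  sigma <- 0.05
  wl <- seq_len(n_pts)
  scans <- lapply(1:6, function(i) nir_spectrum(wl, rnorm(n_pts, 0, sigma)))
  avg <- average_scans(scans)
  expect_equal(sd(avg$absorbance), sigma / sqrt(6), tolerance = 0.05)
})
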