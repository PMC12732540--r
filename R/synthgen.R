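# Synthetic NIR black-tea spectra. Emulates the statistical structure of
# the instrument data the classifier targets: a smooth tea baseline with
# the characteristic absorption bands (weak ~1195 nm, strong 1430-1500 nm,
# catechin-related 1656/1680 nm), a slight overall absorbance decrease plus
# a small colorant-specific band under adulteration, per-sample scatter
# (multiplicative gain + additive offset), and per-scan noise averaged over
# replicate scans.

.default_colorant_bands <- function(amplitude = 0.05) {
  list(
    sunset_yellow = c(center = 1005, width = 18, amplitude = amplitude),
    tartrazine    = c(center = 1210, width = 16, amplitude = amplitude),
    ponceau_4r    = c(center = 1555, width = 20, amplitude = amplitude)
  )
}

#' Synthetic spectra design
#'
#' All knobs of the generator. Defaults mirror the sampling design of the
#' screening study: 45 pure samples plus 100 per colorant for the three azo
#' colorants (345 spectra), colorant concentrations 0.1-0.5 g/kg in 0.05
#' steps, six replicate scans averaged per sample, and band positions at
#' 1195, 1465, 1656 and 1680 nm with the 1430-1500 nm band strongest.
#'
#' @param n_pure number of pure (unadulterated) samples.
#' @param n_per_colorant adulterated samples per listed colorant.
#' @param colorants subset of `c("sunset_yellow","tartrazine","ponceau_4r")`.
#' @param concentrations strictly positive, sorted grid of colorant doses
#'   (g/kg); samples cycle over it so every level is covered nearly
#'   uniformly, surplus going to the low levels.
#' @param band_centers,band_widths,band_amplitudes Gaussian tea-band
#'   parameters (nm, nm, absorbance).
#' @param baseline_offset,baseline_slope linear baseline: absorbance at the
#'   first grid point and drift per nm.
#' @param global_effect fractional absorbance decrease per g/kg of colorant
#'   (the adulteration effect size; multiplies the whole curve).
#' @param colorant_bands named list, one `c(center, width, amplitude)` per
#'   colorant; `amplitude` is absorbance per g/kg added locally.
#' @param scatter_mult_sd,scatter_add_sd per-sample multiplicative gain sd
#'   and additive offset sd (particle-size scatter surrogate).
#' @param noise_sd per-point instrument noise sd of a single scan, before
#'   scan averaging.
#' @param n_scans replicate scans averaged per sample.
#' @param wavelengths measurement grid (nm).
#' @param seed RNG seed; the dataset is a pure function of the design.
#' @return an object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_pure = 45,
                             n_per_colorant = 100,
                             colorants = c("sunset_yellow", "tartrazine",
                                           "ponceau_4r"),
                             concentrations = seq(0.10, 0.50, by = 0.05),
                             band_centers = c(1195, 1465, 1656, 1680),
                             band_widths = c(35, 40, 10, 9),
                             band_amplitudes = c(0.12, 0.40, 0.16, 0.14),
                             baseline_offset = 0.25,
                             baseline_slope = 2e-4,
                             global_effect = 0.05,
                             colorant_bands = .default_colorant_bands(),
                             scatter_mult_sd = 0.01,
                             scatter_add_sd = 0.003,
                             noise_sd = 0.008,
                             n_scans = 6,
                             wavelengths = default_wavelength_grid(),
                             seed = 1L) {
  stopifnot(n_pure >= 0, n_per_colorant >= 0, n_scans >= 1)
  colorants <- as.character(colorants)
  if (!all(colorants %in% setdiff(COLORANT_TAGS, "none"))) {
    stop("colorants must be drawn from the known tags", call. = FALSE)
  }
  if (anyDuplicated(colorants)) stop("duplicate colorant tags", call. = FALSE)
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly positive and sorted", call. = FALSE)
  }
  if (length(band_centers) != length(band_widths) ||
      length(band_centers) != length(band_amplitudes)) {
    stop("band parameter vectors must share one length", call. = FALSE)
  }
  if (any(band_widths <= 0)) stop("band widths must be positive", call. = FALSE)
  if (scatter_mult_sd < 0 || scatter_add_sd < 0 || noise_sd < 0) {
    stop("noise and scatter sds must be non-negative", call. = FALSE)
  }
  missing_bands <- setdiff(colorants, names(colorant_bands))
  if (length(missing_bands)) {
    stop("colorant_bands missing entries for: ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  }
  structure(list(n_pure = as.integer(n_pure),
                 n_per_colorant = as.integer(n_per_colorant),
                 colorants = colorants,
                 concentrations = as.numeric(concentrations),
                 band_centers = band_centers, band_widths = band_widths,
                 band_amplitudes = band_amplitudes,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope,
                 global_effect = global_effect,
                 colorant_bands = colorant_bands,
                 scatter_mult_sd = scatter_mult_sd,
                 scatter_add_sd = scatter_add_sd,
                 noise_sd = noise_sd,
                 n_scans = as.integer(n_scans),
                 wavelengths = as.numeric(wavelengths),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

.gauss_band <- function(wl, center, width, amplitude) {
  amplitude * exp(-0.5 * ((wl - center) / width)^2)
}

#' Deterministic pure-tea baseline curve
#'
#' Linear baseline plus the sum of Gaussian tea bands. With default band
#' amplitudes the 1430-1500 nm band dominates the weak 1170-1220 nm band,
#' so the curve's maximum falls in the 1430-1500 nm window.
#'
#' @param wavelengths grid (nm).
#' @param design a [synthetic_design()].
#' @return absorbance vector, same length as `wavelengths`.
#' @export
tea_baseline <- function(wavelengths, design) {
  stopifnot(inherits(design, "synthetic_design"))
  wl <- as.numeric(wavelengths)
  out <- design$baseline_offset + design$baseline_slope * (wl - wl[1L])
  for (i in seq_along(design$band_centers)) {
    out <- out + .gauss_band(wl, design$band_centers[i],
                             design$band_widths[i], design$band_amplitudes[i])
  }
  out
}

#' Apply a colorant dose to a pure baseline
#'
#' The colorant scales the whole curve down by `1 - global_effect * conc`
#' (the slight absorbance decrease adulteration causes) and adds a small
#' colorant-specific Gaussian band proportional to the dose.
#'
#' @param baseline absorbance vector on `design$wavelengths`.
#' @param colorant one of the design's colorant tags.
#' @param conc dose in g/kg, strictly positive.
#' @param design a [synthetic_design()].
#' @return adulterated absorbance vector.
#' @export
apply_adulteration <- function(baseline, colorant, conc, design) {
  stopifnot(inherits(design, "synthetic_design"))
  if (length(conc) != 1L || !is.finite(conc) || conc <= 0) {
    stop("conc must be a single positive dose (g/kg)", call. = FALSE)
  }
  if (!colorant %in% names(design$colorant_bands)) {
    stop("unknown colorant: ", colorant, call. = FALSE)
  }
  if (length(baseline) != length(design$wavelengths)) {
    stop("baseline must live on the design's wavelength grid", call. = FALSE)
  }
  band <- design$colorant_bands[[colorant]]
  baseline * (1 - design$global_effect * conc) +
    conc * .gauss_band(design$wavelengths, band[["center"]], band[["width"]],
                       band[["amplitude"]])
}

#' Generate a synthetic labelled dataset
#'
#' Produces `n_pure` pure samples followed by `n_per_colorant` adulterated
#' samples per colorant (in the order listed). Each sample draws one
#' multiplicative gain and one additive offset (scatter), then `n_scans`
#' noisy scans are simulated and averaged via [average_scans()].
#' Concentrations cycle over the design grid. The result is a pure function
#' of the design, including its seed.
#'
#' @param design a [synthetic_design()].
#' @return a [spectra_set()].
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  if (length(design$colorants) == 0L && design$n_per_colorant > 0L) {
    stop("n_per_colorant > 0 requires at least one colorant", call. = FALSE)
  }
  wl <- design$wavelengths
  base <- tea_baseline(wl, design)

  plan <- data.frame(colorant = "none", conc = 0,
                     stringsAsFactors = FALSE)[rep(1L, design$n_pure), ]
  for (col in design$colorants) {
    if (design$n_per_colorant > 0L) {
      plan <- rbind(plan, data.frame(
        colorant = col,
        conc = rep_len(design$concentrations, design$n_per_colorant),
        stringsAsFactors = FALSE))
    }
  }
  n <- nrow(plan)
  if (n < 1L) stop("design yields no samples", call. = FALSE)

  counters <- integer(0)
  ids <- character(n)
  ab <- matrix(0.0, n, length(wl))
  with_seed(design$seed, {
    for (s in seq_len(n)) {
      tag <- plan$colorant[s]
      counters[tag] <- if (is.na(counters[tag])) 1L else counters[tag] + 1L
      ids[s] <- sprintf("%s_%03d", if (tag == "none") "pure" else tag,
                        counters[tag])
      clean <- if (tag == "none") base else
        apply_adulteration(base, tag, plan$conc[s], design)
      gain <- 1 + stats::rnorm(1L, 0, design$scatter_mult_sd)
      offset <- stats::rnorm(1L, 0, design$scatter_add_sd)
      sample_curve <- gain * clean + offset
      scans <- lapply(seq_len(design$n_scans), function(k) {
        nir_spectrum(wl, sample_curve +
                       stats::rnorm(length(wl), 0, design$noise_sd))
      })
      ab[s, ] <- average_scans(scans)$absorbance
    }
  })
  spectra_set(wl, ab, as.integer(plan$colorant != "none"), plan$colorant,
              plan$conc, ids)
}
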