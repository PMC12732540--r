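# Domain containers for NIR spectra, CSV interchange, replicate-scan
# averaging. Every other module exchanges data through these types.

#' Recognised colorant tags
#'
#' The three azo colorants covered by the screening task, plus `"none"` for
#' pure (unadulterated) tea.
#' @export
COLORANT_TAGS <- c("none", "sunset_yellow", "tartrazine", "ponceau_4r")

#' Default NIR wavelength grid
#'
#' Handheld NIR spectrometers of the class targeted here cover roughly
#' 900-1700 nm at 3 nm resolution. The exact point count is an instrument
#' convention, so the grid is an explicit value, never assumed: the default
#' runs 900 to 1698 nm in 3 nm steps (267 points).
#'
#' @param from,to,by grid limits and step, in nm.
#' @return numeric vector of wavelengths (nm), strictly increasing.
#' @export
default_wavelength_grid <- function(from = 900, to = 1698, by = 3) {
  seq(from, to, by = by)
}

#' Single NIR spectrum
#'
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm).
#' @param absorbance numeric vector of absorbance values, same length.
#' @return an object of class `nir_spectrum`.
#' @export
nir_spectrum <- function(wavelengths, absorbance) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths) != length(absorbance)) {
    stop("wavelengths and absorbance must have the same length", call. = FALSE)
  }
  if (length(wavelengths) < 1L) {
    stop("a spectrum needs at least one point", call. = FALSE)
  }
  if (!all(is.finite(wavelengths)) || !all(is.finite(absorbance))) {
    stop("spectrum values must all be finite", call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, absorbance = absorbance),
            class = "nir_spectrum")
}

#' @export
print.nir_spectrum <- function(x, ...) {
  cat(sprintf("<nir_spectrum> %d points, %g-%g nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Collection of labelled NIR spectra
#'
#' The universal exchange object: an N x L absorbance matrix on a shared
#' wavelength grid, with per-sample binary adulteration labels, colorant
#' tags, colorant concentrations and unique sample ids.
#'
#' Invariants enforced: label 0 iff colorant `"none"` iff concentration 0;
#' concentrations non-negative; ids unique; N >= 1.
#'
#' @param wavelengths shared grid (nm), strictly increasing.
#' @param absorbance numeric matrix, one row per sample, `length(wavelengths)`
#'   columns.
#' @param labels integer vector of 0 (pure) / 1 (adulterated).
#' @param colorant character vector of tags from [COLORANT_TAGS].
#' @param concentration numeric vector, g/kg; 0 for pure samples.
#' @param sample_id character vector of unique ids.
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, labels, colorant,
                        concentration, sample_id) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  labels <- as.integer(labels)
  colorant <- as.character(colorant)
  concentration <- as.numeric(concentration)
  sample_id <- as.character(sample_id)

  n <- nrow(absorbance)
  if (n < 1L) stop("a spectra_set needs at least one sample", call. = FALSE)
  if (ncol(absorbance) != length(wavelengths)) {
    stop("absorbance must have one column per wavelength", call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("absorbance values must all be finite", call. = FALSE)
  }
  if (length(labels) != n || length(colorant) != n ||
      length(concentration) != n || length(sample_id) != n) {
    stop("labels, colorant, concentration and sample_id must all have length N",
         call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 (pure) or 1 (adulterated)", call. = FALSE)
  }
  if (!all(colorant %in% COLORANT_TAGS)) {
    stop("unknown colorant tag; allowed: ", paste(COLORANT_TAGS, collapse = ", "),
         call. = FALSE)
  }
  if (any(concentration < 0) || !all(is.finite(concentration))) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  pure <- labels == 0L
  if (!identical(pure, colorant == "none") ||
      !identical(pure, concentration == 0)) {
    stop("label 0 must coincide with colorant 'none' and concentration 0",
         call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  rownames(absorbance) <- sample_id
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 labels = labels, colorant = colorant,
                 concentration = concentration, sample_id = sample_id),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%g-%g nm)\n",
              nrow(x$absorbance), ncol(x$absorbance),
              min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  pure: %d, adulterated: %d\n",
              sum(x$labels == 0L), sum(x$labels == 1L)))
  tab <- table(x$colorant)
  cat("  colorants:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset a spectra_set by sample index
#'
#' @param x a `spectra_set`.
#' @param i integer or logical index over samples.
#' @param ... ignored.
#' @return a `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$wavelengths, x$absorbance[i, , drop = FALSE], x$labels[i],
              x$colorant[i], x$concentration[i], x$sample_id[i])
}

#' Number of samples in a spectra_set
#' @param x a `spectra_set`.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  nrow(x$absorbance)
}

.meta_cols <- c("id", "label", "colorant", "concentration")

#' Read a spectra CSV
#'
#' One fixed dialect: comma separator, dot decimals, UTF-8, mandatory header.
#' The header names `id,label,colorant,concentration` followed by one numeric
#' wavelength (nm) per remaining column; column order defines the grid.
#'
#' @param path path to an existing CSV file.
#' @return a validated [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nm <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  nm <- gsub("^\"|\"$", "", nm)
  if (length(nm) < length(.meta_cols) + 1L ||
      !identical(nm[seq_along(.meta_cols)], .meta_cols)) {
    stop("spectra CSV must start with columns ",
         paste(.meta_cols, collapse = ","),
         " followed by wavelength columns", call. = FALSE)
  }
  if (anyDuplicated(nm)) stop("duplicate column names in spectra CSV", call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, sep = ",", dec = ".",
                          colClasses = list(character = c("id", "colorant")),
                          data.table = FALSE)
  wl_names <- nm[-seq_along(.meta_cols)]
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl)) {
    stop("wavelength columns must have numeric names (nm)", call. = FALSE)
  }
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    stop("wavelength columns must be strictly increasing", call. = FALSE)
  }
  ab <- as.matrix(dt[, -seq_along(.meta_cols), drop = FALSE])
  if (!is.numeric(ab)) stop("absorbance values must be numeric", call. = FALSE)
  if (!all(dt$label %in% c(0, 1))) {
    stop("labels must be 0 (pure) or 1 (adulterated)", call. = FALSE)
  }
  spectra_set(wl, ab, dt$label, dt$colorant, dt$concentration, dt$id)
}

#' Write a spectra CSV
#'
#' Inverse of [read_spectra_csv()]; absorbance survives the round trip to at
#' least 12 significant digits.
#'
#' @param set a valid `spectra_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  ab <- set$absorbance
  df <- data.frame(id = set$sample_id, label = set$labels,
                   colorant = set$colorant, concentration = set$concentration,
                   stringsAsFactors = FALSE)
  spec <- as.data.frame(ab)
  names(spec) <- vapply(set$wavelengths,
                        function(w) format(w, digits = 15, trim = TRUE,
                                           scientific = FALSE),
                        character(1))
  out <- cbind(df, spec)
  data.table::fwrite(out, path, sep = ",", dec = ".", quote = "auto")
  invisible(path)
}

#' Average replicate scans of one sample
#'
#' Instrument protocol: each sample is scanned several times (six by
#' default in the sampling design) and the pointwise mean spectrum is used.
#'
#' @param replicates list of [nir_spectrum()] objects on identical grids.
#' @return a single `nir_spectrum`, the pointwise arithmetic mean.
#' @export
average_scans <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 1L) {
    stop("need at least one replicate scan", call. = FALSE)
  }
  if (!all(vapply(replicates, inherits, logical(1), "nir_spectrum"))) {
    stop("all replicates must be nir_spectrum objects", call. = FALSE)
  }
  wl <- replicates[[1L]]$wavelengths
  for (r in replicates[-1L]) {
    if (length(r$wavelengths) != length(wl) || any(r$wavelengths != wl)) {
      stop("replicate scans must share an identical wavelength grid",
           call. = FALSE)
    }
  }
  ab <- vapply(replicates, function(r) r$absorbance, numeric(length(wl)))
  nir_spectrum(wl, rowMeans(matrix(ab, nrow = length(wl))))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
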