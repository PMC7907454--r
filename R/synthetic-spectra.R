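#' Frequency-domain 1H-NMR spectrum object
#'
#' A spectrum is stored in NMR convention: the ppm axis strictly decreasing
#' (high field last), intensities non-negative and finite.
#'
#' @param ppm chemical-shift grid, strictly decreasing.
#' @param intensity intensities, same length as `ppm`.
#' @param sample_id sample identifier.
#' @return an object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "sample") {
  if (length(ppm) != length(intensity))
    stop("ppm and intensity lengths differ")
  if (any(diff(ppm) >= 0)) stop("ppm must be strictly decreasing")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(ppm = ppm, intensity = intensity,
                 sample_id = as.character(sample_id)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum '%s': %d points, %.2f to %.2f ppm>\n",
              x$sample_id, length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' Default acquisition grid
#'
#' 2^15 points spanning -0.5 to 10.5 ppm, stored high-to-low. The span
#' covers the TSP reference at 0 ppm and every library peak.
#'
#' @param n number of points.
#' @param span `(low, high)` ppm bounds.
#' @return numeric vector, strictly decreasing.
#' @export
default_ppm_grid <- function(n = 2^15, span = c(-0.5, 10.5)) {
  seq(span[2], span[1], length.out = n)
}

# Multiplet line offsets (ppm) and binomial relative intensities.
# Adjacent lines sit 0.012 ppm apart; a "multiplet" is rendered as five
# evenly spaced lines.
multiplet_pattern <- function(multiplicity) {
  spacing <- 0.012
  switch(multiplicity,
    singlet   = list(offsets = 0, weights = 1),
    doublet   = list(offsets = spacing * c(-0.5, 0.5), weights = c(1, 1) / 2),
    triplet   = list(offsets = spacing * (-1:1), weights = c(1, 2, 1) / 4),
    quartet   = list(offsets = spacing * c(-1.5, -0.5, 0.5, 1.5),
                     weights = c(1, 3, 3, 1) / 8),
    multiplet = list(offsets = spacing * (-2:2),
                     weights = c(1, 4, 6, 4, 1) / 16),
    stop("unknown multiplicity: ", multiplicity))
}

# Add one Lorentzian line to `acc` (ascending-ppm intensity vector).
# The rendered line is rescaled so that its discrete integral (grid step
# times intensity sum) is exactly `area`, making spectrum integrals
# conserve concentration x proton mass regardless of tail truncation
# (render window +/- `window` ppm); on the uniform grids used here the
# trapezoid integral agrees to ~1e-7 relative.
add_lorentzian <- function(acc, ppm_asc, center, area, fwhm = 0.002,
                           window = 0.8) {
  idx <- which(ppm_asc >= center - window & ppm_asc <= center + window)
  if (length(idx) < 3) return(acc)
  x <- ppm_asc[idx]
  hwhm <- fwhm / 2
  y <- 1 / (1 + ((x - center) / hwhm)^2)
  step <- (ppm_asc[length(ppm_asc)] - ppm_asc[1]) / (length(ppm_asc) - 1)
  a0 <- sum(y) * step
  if (a0 <= 0) return(acc)
  acc[idx] <- acc[idx] + y * (area / a0)
  acc
}

# Gaussian artifact line (e.g. residual water hump), also area-exact.
add_gaussian <- function(acc, ppm_asc, center, area, sd, window = 6 * sd) {
  idx <- which(ppm_asc >= center - window & ppm_asc <= center + window)
  if (length(idx) < 3) return(acc)
  x <- ppm_asc[idx]
  y <- exp(-0.5 * ((x - center) / sd)^2)
  step <- (ppm_asc[length(ppm_asc)] - ppm_asc[1]) / (length(ppm_asc) - 1)
  acc[idx] <- acc[idx] + y * (area / (sum(y) * step))
  acc
}

#' Render fingerprint templates on a grid
#'
#' Each metabolite's template is the sum of its multiplet lines (Lorentzian,
#' FWHM 0.002 ppm), with per-peak total area equal to the peak's proton
#' count, so a template's total integral equals the metabolite's total proton
#' count: intensities scale as concentration x protons.
#'
#' @param library a [fingerprint_library()].
#' @param ppm grid (strictly decreasing, as stored in spectra).
#' @return matrix `length(ppm)` x metabolites (columns named), in storage
#'   (decreasing-ppm) order.
#' @export
render_library_templates <- function(library, ppm) {
  stopifnot(inherits(library, "fingerprint_library"))
  if (length(library$metabolites) == 0) stop("empty fingerprint library")
  ppm_asc <- rev(ppm)
  lo_g <- ppm_asc[1]; hi_g <- ppm_asc[length(ppm_asc)]
  out <- matrix(0, length(ppm), length(library$metabolites))
  colnames(out) <- names(library$metabolites)
  for (j in seq_along(library$metabolites)) {
    m <- library$metabolites[[j]]
    if (any(m$peaks$low < lo_g) || any(m$peaks$high > hi_g))
      stop("grid does not cover a library peak of '", m$name, "'")
    acc <- numeric(length(ppm_asc))
    for (i in seq_len(nrow(m$peaks))) {
      pk <- m$peaks[i, ]
      pat <- multiplet_pattern(pk$multiplicity)
      centers <- (pk$low + pk$high) / 2 + pat$offsets
      for (l in seq_along(centers))
        acc <- add_lorentzian(acc, ppm_asc, centers[l],
                              area = pk$protons * pat$weights[l])
    }
    out[, j] <- rev(acc)
  }
  out
}

# Instrumental artifacts shared by every synthetic spectrum: the TSP
# chemical-shift reference singlet at 0.0 ppm, a residual water hump in
# [4.5, 5.1] and a residual extraction-methanol singlet in [3.33, 3.38].
render_artifacts <- function(ppm, tsp_area = 30, water_area = 100,
                             methanol_area = 3) {
  ppm_asc <- rev(ppm)
  acc <- numeric(length(ppm_asc))
  acc <- add_lorentzian(acc, ppm_asc, 0.0, tsp_area)
  acc <- add_gaussian(acc, ppm_asc, 4.79, water_area, sd = 0.08)
  acc <- add_lorentzian(acc, ppm_asc, 3.355, methanol_area)
  rev(acc)
}

#' Synthesize one plasma 1H-NMR spectrum
#'
#' Forges a frequency-domain spectrum from a concentration vector: the sum
#' over metabolites of `conc_j` times the metabolite's rendered template,
#' plus the TSP reference singlet, a residual water hump and a residual
#' methanol singlet, a global chemical-shift jitter `N(0, shift_jitter_sd)`
#' and additive Gaussian intensity noise (truncated at zero).
#'
#' @param concentrations_row named numeric vector aligned to the library's
#'   metabolite order.
#' @param library a [fingerprint_library()].
#' @param noise_sd intensity noise SD (arbitrary units).
#' @param shift_jitter_sd SD of the per-sample global ppm shift.
#' @param seed integer seed; the spectrum is deterministic given the seed.
#' @param ppm grid, strictly decreasing.
#' @param sample_id sample identifier.
#' @param templates optional pre-rendered template matrix from
#'   [render_library_templates()] (re-used across a cohort for speed).
#' @param artifacts include the TSP/water/methanol artifact signals
#'   (disable to forge pure-mixture spectra for method validation).
#' @return an [nmr_spectrum()].
#' @export
synthesize_spectrum <- function(concentrations_row, library, noise_sd = 0,
                                shift_jitter_sd = 0, seed = 1L,
                                ppm = default_ppm_grid(),
                                sample_id = "sample", templates = NULL,
                                artifacts = TRUE) {
  stopifnot(noise_sd >= 0, shift_jitter_sd >= 0)
  if (is.null(templates)) templates <- render_library_templates(library, ppm)
  if (length(concentrations_row) != ncol(templates))
    stop("concentration vector not aligned to library order")
  if (any(concentrations_row < 0)) stop("negative concentration")
  intensity <- as.numeric(templates %*% concentrations_row)
  if (artifacts) intensity <- intensity + render_artifacts(ppm)
  with_seed(seed, {
    if (shift_jitter_sd > 0) {
      delta <- stats::rnorm(1, 0, shift_jitter_sd)
      intensity <- stats::approx(x = ppm + delta, y = intensity, xout = ppm,
                                 rule = 2)$y
    }
    if (noise_sd > 0)
      intensity <- pmax(intensity +
                          stats::rnorm(length(intensity), 0, noise_sd), 0)
  })
  nmr_spectrum(ppm, intensity, sample_id)
}

#' Synthesize spectra for a whole cohort
#'
#' @param concentrations samples x metabolites matrix (row names used as
#'   sample ids), columns aligned to the library.
#' @param library a [fingerprint_library()].
#' @param noise_sd,shift_jitter_sd,ppm as in [synthesize_spectrum()].
#' @param seed base seed; sample `i` uses `seed + i`.
#' @return a named list of [nmr_spectrum()] objects.
#' @export
synthesize_cohort_spectra <- function(concentrations, library, noise_sd = 10,
                                      shift_jitter_sd = 0.003, seed = 1L,
                                      ppm = default_ppm_grid()) {
  templates <- render_library_templates(library, ppm)
  ids <- rownames(concentrations)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(concentrations)))
  spectra <- lapply(seq_len(nrow(concentrations)), function(i) {
    synthesize_spectrum(concentrations[i, ], library, noise_sd,
                        shift_jitter_sd, seed = seed + i, ppm = ppm,
                        sample_id = ids[i], templates = templates)
  })
  names(spectra) <- ids
  spectra
}

#' Read / write spectrum files
#'
#' Spectra are exchanged as tab-separated two-column files
#' (`ppm<TAB>intensity`) with a single header line `# sample_id=<id>`.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param path file path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum`
#'   returns an [nmr_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sample_id=", spectrum$sample_id), con)
  utils::write.table(
    data.frame(ppm = spectrum$ppm, intensity = spectrum$intensity),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  header <- readLines(path, n = 1)
  id <- sub("^#\\s*sample_id=", "", header)
  dat <- utils::read.table(path, sep = "\t", skip = 1,
                           col.names = c("ppm", "intensity"))
  nmr_spectrum(dat$ppm, dat$intensity, id)
}

# Trapezoid integral of a spectrum over its full (ascending) axis.
spectrum_integral <- function(spectrum) {
  pracma::trapz(rev(spectrum$ppm), rev(spectrum$intensity))
}
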