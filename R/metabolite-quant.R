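#' Quantification mask for fingerprint deconvolution
#'
#' Grid indices inside the analysis span and outside the exclusion ranges.
#' @keywords internal
quant_mask <- function(ppm, span = c(0.5, 10),
                       exclusions = list(c(4.5, 5.1), c(3.33, 3.38))) {
  keep <- ppm >= span[1] & ppm <= span[2]
  for (e in exclusions) keep <- keep & !(ppm > e[1] & ppm < e[2])
  which(keep)
}

#' Build the deconvolution design matrix
#'
#' Renders every library template on the spectrum grid and restricts it to
#' the quantification mask. Columns keep their natural scale (template
#' intensity proportional to concentration x protons), so the non-negative
#' least-squares coefficients against a total-intensity-normalized spectrum
#' are directly proportional to concentration.
#'
#' @param library a [fingerprint_library()].
#' @param ppm spectrum grid (decreasing).
#' @param span,exclusions analysis span and masked ranges.
#' @return list with `A` (masked, column-normalized design), `mask`
#'   (grid indices) and `metabolites`.
#' @export
fingerprint_design <- function(library, ppm, span = c(0.5, 10),
                               exclusions = list(c(4.5, 5.1),
                                                 c(3.33, 3.38))) {
  templates <- render_library_templates(library, ppm)
  mask <- quant_mask(ppm, span, exclusions)
  A <- templates[mask, , drop = FALSE]
  csum <- colSums(A)
  if (any(csum <= 0))
    stop("template(s) with no intensity inside the analysis mask: ",
         paste(colnames(A)[csum <= 0], collapse = ", "))
  # Cholesky factor of the Gram matrix: lets each sample's NNLS be solved
  # in metabolite space (min ||R c - R^-T A's||^2 has the same solution as
  # min ||A c - s||^2); left NULL when the Gram matrix is ill-conditioned.
  R <- tryCatch(chol(crossprod(A)), error = function(e) NULL)
  list(A = A, mask = mask, metabolites = colnames(A), chol = R)
}

#' Quantify metabolites by fingerprint deconvolution
#'
#' Solves `min || A c - s ||^2` subject to `c >= 0`, where the columns of
#' `A` are the fingerprint templates rendered on the masked grid and `s` is
#' the spectrum normalized to unit total masked intensity. The coefficients
#' are unit-less relative concentrations "in function of the whole
#' spectrum": exactly proportional to the true concentrations for a
#' noiseless mixture of library metabolites.
#'
#' @param spectrum a calibrated [nmr_spectrum()].
#' @param library a [fingerprint_library()].
#' @param design optional pre-built [fingerprint_design()] (re-used across a
#'   cohort).
#' @param span,exclusions forwarded to [fingerprint_design()].
#' @return named non-negative numeric vector, one entry per metabolite.
#' @export
quantify_by_fingerprint <- function(spectrum, library, design = NULL,
                                    span = c(0.5, 10),
                                    exclusions = list(c(4.5, 5.1),
                                                      c(3.33, 3.38))) {
  if (is.null(design))
    design <- fingerprint_design(library, spectrum$ppm, span, exclusions)
  s <- spectrum$intensity[design$mask]
  tot <- sum(s)
  if (tot <= 0) stop("spectrum has no intensity inside the analysis mask")
  fit <- if (!is.null(design$chol)) {
    b <- backsolve(design$chol, crossprod(design$A, s / tot),
                   transpose = TRUE)
    pracma::lsqnonneg(design$chol, as.numeric(b))
  } else {
    pracma::lsqnonneg(design$A, s / tot)
  }
  stats::setNames(fit$x, design$metabolites)
}

#' Quantify a cohort of spectra
#'
#' @param spectra list of calibrated [nmr_spectrum()] on a common grid.
#' @param library a [fingerprint_library()].
#' @param span,exclusions forwarded to [fingerprint_design()].
#' @return samples x metabolites matrix of relative concentrations.
#' @export
quantify_cohort <- function(spectra, library, span = c(0.5, 10),
                            exclusions = list(c(4.5, 5.1), c(3.33, 3.38))) {
  design <- fingerprint_design(library, spectra[[1]]$ppm, span, exclusions)
  rows <- lapply(spectra, quantify_by_fingerprint, library = library,
                 design = design)
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(spectra, `[[`, character(1), "sample_id")
  out
}

#' Presence filter
#'
#' Keeps a metabolite if, at one or more sampling days, it is present
#' (value above `threshold`) in at least `min_fraction` of that day's
#' samples.
#'
#' @param table samples x metabolites matrix (row names = sample ids).
#' @param phenotypes data frame with `animal_id` and `day` covering every
#'   row of `table`.
#' @param min_fraction minimum within-day presence fraction.
#' @param threshold presence detection threshold (strictly-above rule).
#' @return the filtered matrix, column order preserved.
#' @export
presence_filter <- function(table, phenotypes, min_fraction = 0.5,
                            threshold = 0) {
  idx <- match(rownames(table), phenotypes$animal_id)
  if (any(is.na(idx))) stop("unknown sample in concentration table")
  day <- phenotypes$day[idx]
  keep <- vapply(seq_len(ncol(table)), function(j) {
    frac <- tapply(table[, j] > threshold, day, mean)
    any(frac >= min_fraction)
  }, logical(1))
  table[, keep, drop = FALSE]
}

#' Map fingerprint peaks to retained buckets
#'
#' For every peak of every metabolite, finds the retained buckets whose
#' interval intersects `[low - tolerance, high + tolerance]` (closed-interval
#' overlap, so a bucket touching the peak boundary is included). Peaks that
#' map to no surviving bucket (e.g. falling inside the water exclusion) are
#' flagged, not errors.
#'
#' @param bucket_labels numeric bucket centers (decreasing), e.g.
#'   `bucket_table$bucket_labels`.
#' @param library a [fingerprint_library()].
#' @param tolerance ppm widening applied to each peak range.
#' @param interval bucket width used to reconstruct bucket intervals.
#' @return named list (per metabolite) of lists with `peak_buckets` (one
#'   integer vector of bucket indices per peak) and `unmapped` (logical per
#'   peak).
#' @export
map_buckets_to_metabolites <- function(bucket_labels, library,
                                       tolerance = 0, interval = 0.01) {
  stopifnot(tolerance >= 0)
  b_lo <- bucket_labels - interval / 2
  b_hi <- bucket_labels + interval / 2
  eps <- 1e-9
  lapply(library$metabolites, function(m) {
    peak_buckets <- lapply(seq_len(nrow(m$peaks)), function(i) {
      lo <- m$peaks$low[i] - tolerance
      hi <- m$peaks$high[i] + tolerance
      which(b_lo <= hi + eps & b_hi >= lo - eps)
    })
    list(peak_buckets = peak_buckets,
         unmapped = lengths(peak_buckets) == 0)
  })
}

#' Relative concentration of a metabolite from bucket data
#'
#' `RC = mean over mapped peaks i of (sum of bucket intensities of peak i) /
#' (proton count of peak i)`; computed from normalized buckets, so RC is
#' unit-less and invariant to the spectrum's overall scale. Peaks with no
#' surviving buckets are skipped from the mean.
#'
#' @param bucket_row normalized bucket intensity vector for one sample.
#' @param fingerprint one metabolite entry of a [fingerprint_library()].
#' @param mapping this metabolite's entry from
#'   [map_buckets_to_metabolites()].
#' @return the RC value (unit-less).
#' @export
relative_concentration <- function(bucket_row, fingerprint, mapping) {
  ok <- !mapping$unmapped
  if (!any(ok)) stop("all peaks of '", fingerprint$name, "' are unmapped")
  terms <- vapply(which(ok), function(i) {
    sum(bucket_row[mapping$peak_buckets[[i]]]) / fingerprint$peaks$protons[i]
  }, numeric(1))
  mean(terms)
}

#' Relative-concentration table for a set of metabolites
#'
#' @param bucket_table a `bucket_table` (normalized intensities are used).
#' @param library a [fingerprint_library()].
#' @param metabolites metabolite names to score (default: all in the
#'   library); metabolites whose every peak is unmapped are dropped with a
#'   warning.
#' @param tolerance,interval forwarded to [map_buckets_to_metabolites()].
#' @return samples x metabolites matrix of RC values.
#' @export
rc_table <- function(bucket_table, library, metabolites = NULL,
                     tolerance = 0, interval = NULL) {
  if (is.null(interval))
    interval <- round(abs(diff(bucket_table$bucket_labels[1:2])), 10)
  if (is.null(metabolites)) metabolites <- names(library$metabolites)
  mapping <- map_buckets_to_metabolites(bucket_table$bucket_labels, library,
                                        tolerance, interval)
  usable <- metabolites[vapply(metabolites, function(nm) {
    !all(mapping[[nm]]$unmapped)
  }, logical(1))]
  if (length(usable) < length(metabolites))
    warning("dropped fully-unmapped metabolite(s): ",
            paste(setdiff(metabolites, usable), collapse = ", "))
  out <- vapply(usable, function(nm) {
    apply(bucket_table$normalized, 1, relative_concentration,
          fingerprint = library$metabolites[[nm]], mapping = mapping[[nm]])
  }, numeric(nrow(bucket_table$normalized)))
  out <- matrix(out, nrow = nrow(bucket_table$normalized),
                dimnames = list(bucket_table$sample_ids, usable))
  out
}
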