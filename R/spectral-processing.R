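#' Bucket grid definition
#'
#' Fixed-width bucketing grid: contiguous `interval`-wide ppm bins covering
#' `span`, minus any bin with positive-measure overlap with an exclusion
#' range (residual water and extraction methanol by default). With the
#' default settings the grid holds 950 bins of which 885 are retained
#' (60 dropped for water 4.5--5.1, 5 for methanol 3.33--3.38).
#'
#' @param interval bucket width, ppm.
#' @param span `(low, high)` ppm range to bucket.
#' @param exclusions list of `(low, high)` ppm ranges to drop.
#' @return an object of class `bucket_grid` with elements `lo`, `hi`,
#'   `center` (per bucket, decreasing ppm order), `retained` (logical) and
#'   the input settings.
#' @export
bucket_grid <- function(interval = 0.01, span = c(0.5, 10),
                        exclusions = list(c(4.5, 5.1), c(3.33, 3.38))) {
  stopifnot(interval > 0, span[1] < span[2])
  exclusions <- lapply(exclusions, function(e) sort(as.numeric(e)))
  if (length(exclusions) > 1) {
    ord <- order(vapply(exclusions, `[`, numeric(1), 1))
    exclusions <- exclusions[ord]
    for (i in seq_along(exclusions)[-1])
      if (exclusions[[i]][1] < exclusions[[i - 1]][2])
        stop("exclusion ranges overlap; merge them first")
  }
  n <- round((span[2] - span[1]) / interval)
  lo <- round(span[1] + (seq_len(n) - 1) * interval, 10)
  hi <- round(lo + interval, 10)
  retained <- rep(TRUE, n)
  eps <- 1e-9
  for (e in exclusions)
    retained <- retained & !(lo < e[2] - eps & hi > e[1] + eps)
  # store in decreasing-ppm order to match spectrum storage
  ord <- order(lo, decreasing = TRUE)
  structure(list(lo = lo[ord], hi = hi[ord],
                 center = round((lo + hi)[ord] / 2, 10),
                 retained = retained[ord],
                 interval = interval, span = span, exclusions = exclusions),
            class = "bucket_grid")
}

#' @export
print.bucket_grid <- function(x, ...) {
  cat(sprintf(
    "Bucket grid: %.3g ppm bins over [%g, %g]; %d total, %d retained\n",
    x$interval, x$span[1], x$span[2], length(x$lo), sum(x$retained)))
  invisible(x)
}

# Integer-step shift of an intensity vector along the stored
# (decreasing-ppm) grid; k > 0 moves features toward lower ppm.
shift_intensity <- function(intensity, k) {
  n <- length(intensity)
  out <- numeric(n)
  if (k >= 0) {
    if (k < n) out[(1 + k):n] <- intensity[1:(n - k)]
  } else {
    k <- -k
    if (k < n) out[1:(n - k)] <- intensity[(1 + k):n]
  }
  out
}

#' Calibrate the chemical-shift axis on the TSP reference
#'
#' Locates the tallest peak inside `search_window` (the TSP singlet) and
#' shifts the spectrum by an integer number of grid steps so that its apex
#' sits at 0.0 ppm (any sub-grid remainder, below half a step, is ignored so
#' all spectra stay on the common grid).
#'
#' @param spectrum an [nmr_spectrum()].
#' @param search_window `(low, high)` ppm window expected to contain TSP.
#' @return the calibrated [nmr_spectrum()], with the applied shift (ppm) in
#'   attribute `"calibration_shift"`.
#' @export
calibrate_to_tsp <- function(spectrum, search_window = c(-0.2, 0.2)) {
  win <- which(spectrum$ppm >= search_window[1] &
                 spectrum$ppm <= search_window[2])
  if (length(win) < 3) stop("search window outside the spectrum grid")
  wint <- spectrum$intensity[win]
  floor_est <- stats::median(wint)
  spread <- stats::sd(wint)
  if (!is.finite(spread) || spread == 0 ||
      max(wint) < floor_est + 5 * spread)
    stop("no peak above the noise floor in the TSP search window")
  apex_ppm <- spectrum$ppm[win[which.max(wint)]]
  step <- abs(spectrum$ppm[1] - spectrum$ppm[2])
  k <- round(apex_ppm / step)
  out <- nmr_spectrum(spectrum$ppm, shift_intensity(spectrum$intensity, k),
                      spectrum$sample_id)
  attr(out, "calibration_shift") <- -k * step
  out
}

#' Align spectra by global cross-correlation
#'
#' Shifts every spectrum by the integer-grid lag (within `max_shift` ppm)
#' that maximizes its cross-correlation with a reference (the pointwise
#' median spectrum by default).
#'
#' @param spectra list of [nmr_spectrum()] on identical grids.
#' @param reference optional reference intensity vector; defaults to the
#'   pointwise median across spectra.
#' @param max_shift maximum allowed shift, ppm.
#' @return list of aligned spectra; the applied corrections (ppm) are in
#'   attribute `"lags_ppm"`.
#' @export
align_spectra <- function(spectra, reference = NULL, max_shift = 0.05) {
  stopifnot(length(spectra) >= 2)
  ppm <- spectra[[1]]$ppm
  for (s in spectra)
    if (!isTRUE(all.equal(s$ppm, ppm)))
      stop("spectra are not on identical grids")
  intens <- vapply(spectra, `[[`, numeric(length(ppm)), "intensity")
  if (is.null(reference)) reference <- apply(intens, 1, stats::median)
  step <- abs(ppm[1] - ppm[2])
  lags <- -round(max_shift / step):round(max_shift / step)
  out <- vector("list", length(spectra))
  applied <- numeric(length(spectra))
  for (i in seq_along(spectra)) {
    score <- vapply(lags, function(k) {
      sum(shift_intensity(intens[, i], k) * reference)
    }, numeric(1))
    k <- lags[which.max(score)]
    out[[i]] <- nmr_spectrum(ppm, shift_intensity(intens[, i], k),
                             spectra[[i]]$sample_id)
    applied[i] <- k * step * sign_ppm_direction(ppm)
  }
  names(out) <- names(spectra)
  attr(out, "lags_ppm") <- applied
  out
}

# On a decreasing-ppm grid a positive index shift moves features to lower
# ppm; report corrections on the ppm axis (negative = moved down in ppm).
sign_ppm_direction <- function(ppm) if (ppm[1] > ppm[2]) -1 else 1

#' Bucket a spectrum
#'
#' Integrates the spectrum curve (trapezoid rule) over each retained bucket
#' `[lo, hi)` of the grid; bucket edges falling between grid points are
#' handled by linear interpolation of the cumulative integral.
#'
#' @param spectrum an [nmr_spectrum()] covering the grid span.
#' @param grid a [bucket_grid()].
#' @return named numeric vector of raw bucket intensities for the retained
#'   buckets, in decreasing-ppm order; names are bucket centers with three
#'   decimals.
#' @export
bucketize <- function(spectrum, grid) {
  stopifnot(inherits(grid, "bucket_grid"))
  ppm_asc <- rev(spectrum$ppm)
  if (ppm_asc[1] > grid$span[1] || ppm_asc[length(ppm_asc)] < grid$span[2])
    stop("spectrum does not cover the bucket span")
  step <- ppm_asc[2] - ppm_asc[1]
  if (step > grid$interval)
    stop("spectrum grid is coarser than the bucket width")
  y <- rev(spectrum$intensity)
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(ppm_asc)))
  F <- stats::approxfun(ppm_asc, cum, rule = 2)
  keep <- grid$retained
  vals <- F(grid$hi[keep]) - F(grid$lo[keep])
  stats::setNames(vals, sprintf("%.3f", grid$center[keep]))
}

#' Bucket a set of spectra into a raw intensity matrix
#'
#' @param spectra list of [nmr_spectrum()].
#' @param grid a [bucket_grid()].
#' @return samples x buckets matrix of raw intensities (row names = sample
#'   ids, column names = bucket centers).
#' @export
bucketize_spectra <- function(spectra, grid) {
  rows <- lapply(spectra, bucketize, grid = grid)
  raw <- do.call(rbind, rows)
  rownames(raw) <- vapply(spectra, `[[`, character(1), "sample_id")
  raw
}

#' Normalize bucket intensities to the whole-spectrum intensity
#'
#' `normalized[i, k] = raw[i, k] / sum_k raw[i, k]`; the whole-spectrum
#' intensity is the sum over retained buckets (solvent regions are already
#' excluded).
#'
#' @param raw samples x buckets matrix of raw bucket intensities.
#' @return an object of class `bucket_table` with `sample_ids`,
#'   `bucket_labels` (numeric centers, decreasing), `raw` and `normalized`.
#' @export
normalize_buckets <- function(raw) {
  raw <- as.matrix(raw)
  totals <- rowSums(raw)
  if (any(totals <= 0)) stop("a sample has non-positive total intensity")
  labels <- as.numeric(colnames(raw))
  if (any(is.na(labels)) || any(diff(labels) >= 0))
    stop("bucket labels must be strictly decreasing ppm centers")
  structure(list(sample_ids = rownames(raw),
                 bucket_labels = labels,
                 raw = raw,
                 normalized = raw / totals),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("Bucket table: %d samples x %d buckets (%.3f to %.3f ppm)\n",
              nrow(x$raw), ncol(x$raw),
              max(x$bucket_labels), min(x$bucket_labels)))
  invisible(x)
}

#' Write a bucket table to CSV
#'
#' Writes `buckets_raw.csv` and `buckets_normalized.csv`: first column
#' `sample_id`, remaining headers the bucket centers (three decimals).
#'
#' @param table a `bucket_table`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bucket_table <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (what in c("raw", "normalized")) {
    df <- data.frame(sample_id = table$sample_ids,
                     table[[what]], check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0("buckets_", what, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
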