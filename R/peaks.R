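#' Mean spectrum of a cohort or cube
#'
#' Per-bin arithmetic mean over all spectra/pixels on the common axis; the
#' input to gradient peak picking.
#'
#' @param x a [SpectrumCohort-class] or [MSIDataCube-class].
#' @return a [MassSpectrum-class].
#' @export
meanSpectrum <- function(x) {
    stopifnot(is(x, "SpectrumCohort") || is(x, "MSIDataCube"))
    m <- intensities(x)
    .assert(nrow(m) > 0, "cannot take the mean spectrum of an empty object")
    MassSpectrum(mz(x), colMeans(m))
}

#' Gradient peak picking
#'
#' Detects local maxima of a profile spectrum by first-difference sign change
#' (intensity rising into a bin and falling after it). Plateau maxima (runs
#' of equal intensity higher than both neighbours) report the plateau's
#' centre bin, rounding down on even-length plateaus. Peaks below
#' `min_intensity` are dropped.
#'
#' @param spectrum a [MassSpectrum-class] on a uniform axis.
#' @param min_intensity intensity floor (default 0 keeps all maxima).
#' @return a [PeakList-class].
#' @export
gradientPeakPick <- function(spectrum, min_intensity = 0) {
    stopifnot(is(spectrum, "MassSpectrum"))
    y <- spectrum@intensity
    .assert(length(y) >= 3, "spectrum too short for peak picking (< 3 bins)")
    r <- rle(y)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- length(r$values)
    keep <- logical(k)
    if (k >= 3)
        keep[2:(k - 1)] <- r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                           r$values[2:(k - 1)] > r$values[3:k]
    keep <- keep & r$values >= min_intensity
    centre <- floor((starts + ends) / 2)
    idx <- centre[keep]
    PeakList(spectrum@mz[idx], y[idx])
}

#' Keep the N most intense peaks
#'
#' Selects the `n` highest-intensity peaks (ties broken toward lower m/z) and
#' returns them sorted by m/z with recomputed ranks. Idempotent; if fewer
#' than `n` peaks exist the input is returned unchanged.
#'
#' @param peaks a [PeakList-class].
#' @param n number of peaks to keep (>= 1).
#' @return a [PeakList-class].
#' @export
topNPeaks <- function(peaks, n) {
    stopifnot(is(peaks, "PeakList"))
    .assert(n >= 1, "n must be >= 1")
    if (length(peaks@mz) <= n) return(peaks)
    sel <- order(-peaks@intensity, peaks@mz)[seq_len(n)]
    PeakList(peaks@mz[sel], peaks@intensity[sel])
}

#' Reduce a dense cube or cohort to peak feature space
#'
#' For each picked peak, the feature value of a pixel/spectrum is the summed
#' intensity of the raw bins within `tol` Da of the peak m/z. Bins falling
#' inside the window of more than one peak are assigned to the nearest peak
#' (a warning reports how many windows overlapped).
#'
#' @param x an [MSIDataCube-class] or [SpectrumCohort-class] on a dense axis.
#' @param peaks a non-empty [PeakList-class].
#' @param tol half-window in Da; NULL uses half the median inter-peak gap,
#'   capped at 0.05 Da.
#' @return object of the same class with feature axis `mz(peaks)`.
#' @export
buildDataCube <- function(x, peaks, tol = NULL) {
    stopifnot(is(x, "MSIDataCube") || is(x, "SpectrumCohort"),
              is(peaks, "PeakList"))
    .assert(length(peaks@mz) > 0, "peak list is empty")
    if (is.null(tol)) {
        gaps <- diff(peaks@mz)
        tol <- if (length(gaps)) min(stats::median(gaps) / 2, 0.05) else 0.05
    }
    .assert(tol > 0, "tol must be positive")
    axis <- mz(x)
    # nearest peak for every bin, then keep bins within tol of it
    nearest <- findInterval(axis, peaks@mz)
    lo <- pmax(nearest, 1L)
    hi <- pmin(nearest + 1L, length(peaks@mz))
    d_lo <- abs(axis - peaks@mz[lo])
    d_hi <- abs(axis - peaks@mz[hi])
    near <- ifelse(d_hi < d_lo, hi, lo)
    dist <- pmin(d_lo, d_hi)
    inwin <- dist <= tol
    if (length(peaks@mz) > 1 && any(diff(peaks@mz) < 2 * tol))
        warning(sum(diff(peaks@mz) < 2 * tol),
                " overlapping peak windows resolved by nearest-peak assignment")
    m <- intensities(x)
    feat <- matrix(0, nrow(m), length(peaks@mz))
    if (any(inwin)) {
        grp <- near[inwin]
        sub <- m[, inwin, drop = FALSE]
        agg <- t(rowsum(t(sub), group = grp))
        feat[, as.integer(colnames(agg))] <- agg
    }
    if (is(x, "MSIDataCube"))
        MSIDataCube(peaks@mz, feat, x@coords, x@dim, x@metadata)
    else
        SpectrumCohort(peaks@mz, feat, x@sampleData, massWindow = x@massWindow)
}
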