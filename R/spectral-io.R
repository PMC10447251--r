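#' Build a uniform m/z axis
#'
#' Constructs the common axis used for interpolation rebinning: uniformly
#' spaced points from the lower to the upper window bound (inclusive) with the
#' given bin width, `floor((upper - lower) / bin_width) + 1` points in total.
#'
#' @param mass_window numeric(2), window c(lower, upper) in Da, lower <= upper.
#' @param bin_width positive bin width in Da (default 0.001).
#'
#' @return numeric vector of m/z values with constant spacing.
#' @examples
#' length(buildMzAxis(c(50, 50.01), 0.001))  # 11
#' @export
buildMzAxis <- function(mass_window, bin_width = 0.001) {
    .assert(is.numeric(bin_width) && length(bin_width) == 1 && bin_width > 0,
            "bin_width must be a positive number")
    .assert(length(mass_window) == 2 && mass_window[1] <= mass_window[2],
            "mass_window must be c(lower, upper) with lower <= upper")
    n <- floor((mass_window[2] - mass_window[1]) / bin_width + 1e-9) + 1
    mass_window[1] + (seq_len(n) - 1) * bin_width
}

#' Interpolation rebinning onto a target axis
#'
#' Linearly interpolates a profile spectrum onto a new m/z axis so that all
#' spectra share one axis before a mean spectrum is formed. Points outside the
#' source range get intensity 0 (absent signal, not extrapolation).
#'
#' @param spectrum a [MassSpectrum-class].
#' @param target_axis strictly increasing numeric m/z vector.
#'
#' @return a [MassSpectrum-class] on `target_axis`, metadata preserved.
#' @export
rebin <- function(spectrum, target_axis) {
    stopifnot(is(spectrum, "MassSpectrum"))
    .assert(length(spectrum@mz) > 0, "cannot rebin an empty spectrum")
    .assert(all(diff(target_axis) > 0), "target_axis must be strictly increasing")
    if (length(spectrum@mz) == 1L) {
        y <- ifelse(target_axis == spectrum@mz, spectrum@intensity, 0)
    } else {
        y <- stats::approx(spectrum@mz, spectrum@intensity, xout = target_axis,
                           method = "linear", yleft = 0, yright = 0)$y
    }
    y[y < 0] <- 0
    MassSpectrum(target_axis, y, spectrum@meta)
}

#' Rebin every spectrum in a list onto a common axis
#'
#' @param spectra list of [MassSpectrum-class] objects.
#' @param mass_window analysis window in Da.
#' @param bin_width bin width in Da.
#' @return a [SpectrumCohort-class] on the axis built by [buildMzAxis()].
#' @export
rebinCohort <- function(spectra, mass_window, bin_width = 0.001) {
    .assert(length(spectra) > 0, "no spectra supplied")
    axis <- buildMzAxis(mass_window, bin_width)
    mat <- t(vapply(spectra, function(s) rebin(s, axis)@intensity,
                    numeric(length(axis))))
    meta <- do.call(rbind, lapply(seq_along(spectra), function(i) {
        m <- spectra[[i]]@meta
        data.frame(sample_id = if (!is.null(m$sample_id)) m$sample_id
                               else sprintf("spectrum_%03d", i),
                   patient_id = if (!is.null(m$patient_id)) m$patient_id else NA,
                   group = if (!is.null(m$group)) m$group else NA,
                   sex = if (!is.null(m$sex)) m$sex else NA,
                   replicate = if (!is.null(m$replicate)) m$replicate else 1L,
                   stringsAsFactors = FALSE)
    }))
    SpectrumCohort(axis, mat, meta, massWindow = mass_window)
}

#' Restrict a cohort to a mass window
#'
#' Slices the common axis to `[lower, upper]` before analysis, mirroring the
#' per-figure analysis windows (e.g. m/z 600-1500 for REIMS lipid profiles).
#'
#' @param cohort a [SpectrumCohort-class].
#' @param mass_window numeric(2) window in Da.
#' @return the restricted [SpectrumCohort-class].
#' @export
restrictMassWindow <- function(cohort, mass_window) {
    stopifnot(is(cohort, "SpectrumCohort"))
    .assert(length(mass_window) == 2 && mass_window[1] <= mass_window[2],
            "mass_window must be c(lower, upper)")
    keep <- cohort@mz >= mass_window[1] & cohort@mz <= mass_window[2]
    .assert(any(keep), "no m/z bins inside the requested window")
    SpectrumCohort(cohort@mz[keep], cohort@intensities[, keep, drop = FALSE],
                   cohort@sampleData, massWindow = mass_window)
}

#' l2 (Euclidean) normalisation of cohort spectra
#'
#' Divides every spectrum (row) by its Euclidean norm so that each row has
#' unit l2 norm, the normalisation applied before t-SNE and clustering.
#' Idempotent. An all-zero spectrum cannot be normalised and raises an error
#' naming the offending sample.
#'
#' @param cohort a [SpectrumCohort-class] (or plain matrix).
#' @return object of the same type with unit-norm rows.
#' @export
l2Normalize <- function(cohort) {
    x <- if (is(cohort, "SpectrumCohort")) cohort@intensities else
         as.matrix(cohort)
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) {
        bad <- which(nrm == 0)
        ids <- if (is(cohort, "SpectrumCohort"))
                   cohort@sampleData$sample_id[bad] else as.character(bad)
        stop("cannot l2-normalize all-zero spectra: ",
             paste(ids, collapse = ", "), call. = FALSE)
    }
    x <- x / nrm
    if (is(cohort, "SpectrumCohort")) {
        cohort@intensities <- x
        cohort
    } else x
}

#' Write / read a cohort as TSV
#'
#' The interchange format for cohorts is a pair of TSV files: an intensity
#' table (rows = spectra, columns = m/z bins, header row carries the axis) and
#' a metadata table (one row per spectrum). `readCohort()` reverses
#' `writeCohort()` exactly up to numeric formatting.
#'
#' @param cohort a [SpectrumCohort-class].
#' @param path path of the intensity TSV; the metadata table is written next
#'   to it with suffix `_meta.tsv`.
#' @return `writeCohort()` returns `path` invisibly; `readCohort()` a
#'   [SpectrumCohort-class].
#' @export
writeCohort <- function(cohort, path) {
    stopifnot(is(cohort, "SpectrumCohort"))
    mat <- cohort@intensities
    colnames(mat) <- sprintf("%.6f", cohort@mz)
    utils::write.table(mat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    meta_path <- sub("\\.tsv$", "_meta.tsv", path)
    if (identical(meta_path, path)) meta_path <- paste0(path, "_meta.tsv")
    utils::write.table(cohort@sampleData, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
    mat <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                       check.names = FALSE))
    meta_path <- sub("\\.tsv$", "_meta.tsv", path)
    if (identical(meta_path, path)) meta_path <- paste0(path, "_meta.tsv")
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    axis <- as.numeric(colnames(mat))
    dimnames(mat) <- NULL
    SpectrumCohort(axis, mat, meta, massWindow = range(axis))
}

#' Per-spectrum metadata constructor
#'
#' Convenience builder for the metadata attached to a [MassSpectrum-class].
#'
#' @param sample_id non-empty sample identifier.
#' @param patient_id optional patient identifier.
#' @param group group label (genotype or mutation status).
#' @param sex optional "M"/"F".
#' @param replicate technical replicate index.
#' @param polarity "positive" or "negative".
#' @param modality "REIMS", "DESI" or "MALDI".
#' @return a named list.
#' @export
sampleMeta <- function(sample_id, patient_id = NULL, group = NULL, sex = NULL,
                       replicate = 1L,
                       polarity = c("negative", "positive"),
                       modality = c("REIMS", "DESI", "MALDI")) {
    .assert(is.character(sample_id) && nzchar(sample_id),
            "sample_id must be a non-empty string")
    list(sample_id = sample_id, patient_id = patient_id, group = group,
         sex = sex, replicate = as.integer(replicate),
         polarity = match.arg(polarity), modality = match.arg(modality))
}
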