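#' @import methods
NULL

#' MassSpectrum: a single profile mass spectrum
#'
#' Holds one profile spectrum: an ascending m/z axis (Da), non-negative
#' intensities in arbitrary units, and free-form sample metadata.
#'
#' @slot mz numeric, strictly increasing m/z axis in Da.
#' @slot intensity numeric, non-negative intensities, same length as `mz`.
#' @slot meta list of sample metadata (see [sampleMeta()]).
#'
#' @exportClass MassSpectrum
setClass("MassSpectrum",
    slots = c(mz = "numeric", intensity = "numeric", meta = "list"))

setValidity("MassSpectrum", function(object) {
    msg <- character()
    if (length(object@mz) != length(object@intensity))
        msg <- c(msg, "mz and intensity must have equal length")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
        msg <- c(msg, "mz must be strictly increasing")
    if (length(object@intensity) && any(object@intensity < 0, na.rm = TRUE))
        msg <- c(msg, "intensities must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @param mz,intensity numeric vectors of equal length.
#' @param meta list of metadata fields.
#' @rdname MassSpectrum-class
#' @export
MassSpectrum <- function(mz, intensity, meta = list()) {
    new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
        meta = meta)
}

#' SpectrumCohort: a set of spectra on a shared m/z axis
#'
#' A cohort of profile spectra interpolated onto one common axis, stored as a
#' spectra-by-bins matrix with one metadata row per spectrum and the mass
#' window the analysis is restricted to.
#'
#' @slot mz numeric, the shared ascending m/z axis (Da).
#' @slot intensities matrix, spectra in rows, m/z bins in columns.
#' @slot sampleData data.frame with one row per spectrum; expected columns
#'   include `sample_id`, `patient_id`, `group`, `sex`, `replicate`,
#'   `polarity`, `modality` (missing optional fields allowed).
#' @slot massWindow numeric(2), the analysis mass window in Da.
#'
#' @exportClass SpectrumCohort
setClass("SpectrumCohort",
    slots = c(mz = "numeric", intensities = "matrix",
              sampleData = "data.frame", massWindow = "numeric"))

setValidity("SpectrumCohort", function(object) {
    msg <- character()
    if (ncol(object@intensities) != length(object@mz))
        msg <- c(msg, "intensity matrix must have one column per m/z bin")
    if (nrow(object@intensities) != nrow(object@sampleData))
        msg <- c(msg, "sampleData must have one row per spectrum")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
        msg <- c(msg, "common m/z axis must be strictly increasing")
    if (length(object@massWindow) != 2L ||
        object@massWindow[1L] > object@massWindow[2L])
        msg <- c(msg, "massWindow must be c(lower, upper) with lower <= upper")
    if (length(object@mz) &&
        (min(object@mz) < object@massWindow[1L] - 1e-9 ||
         max(object@mz) > object@massWindow[2L] + 1e-9))
        msg <- c(msg, "common m/z axis must lie within massWindow")
    if (!"sample_id" %in% colnames(object@sampleData))
        msg <- c(msg, "sampleData must contain a sample_id column")
    if (length(msg)) msg else TRUE
})

#' @param mz shared m/z axis.
#' @param intensities spectra-by-bins matrix.
#' @param sampleData per-spectrum metadata data.frame.
#' @param massWindow analysis window; defaults to the axis range.
#' @rdname SpectrumCohort-class
#' @export
SpectrumCohort <- function(mz, intensities, sampleData,
                           massWindow = range(mz)) {
    new("SpectrumCohort", mz = as.numeric(mz),
        intensities = as.matrix(intensities),
        sampleData = as.data.frame(sampleData, stringsAsFactors = FALSE),
        massWindow = as.numeric(massWindow))
}

#' MSIDataCube: pixel-indexed spectral data from mass spectrometry imaging
#'
#' Stores one intensity vector per pixel (profile bins or peak features on a
#' shared axis), 0-based row-major pixel coordinates, and the image grid size.
#'
#' @slot mz numeric, shared feature axis in Da (dense bins or peak m/z).
#' @slot intensities matrix, pixels in rows, features in columns.
#' @slot coords integer matrix (pixels x 2) of 0-based (x, y) positions.
#' @slot dim integer(2), image width and height in pixels.
#' @slot metadata list; may carry ground-truth compartment maps and masks.
#'
#' @exportClass MSIDataCube
setClass("MSIDataCube",
    slots = c(mz = "numeric", intensities = "matrix", coords = "matrix",
              dim = "integer", metadata = "list"))

setValidity("MSIDataCube", function(object) {
    msg <- character()
    if (nrow(object@intensities) != nrow(object@coords))
        msg <- c(msg, "one coordinate row per pixel required")
    if (ncol(object@coords) != 2L)
        msg <- c(msg, "coords must have two columns (x, y)")
    if (ncol(object@intensities) != length(object@mz))
        msg <- c(msg, "one m/z value per feature column required")
    if (length(object@dim) != 2L || any(object@dim < 1L))
        msg <- c(msg, "dim must be positive width and height")
    if (nrow(object@coords) &&
        (any(object@coords < 0L) ||
         any(object@coords[, 1L] >= object@dim[1L]) ||
         any(object@coords[, 2L] >= object@dim[2L])))
        msg <- c(msg, "coords must be 0-based and inside the image grid")
    if (length(msg)) msg else TRUE
})

#' @param mz feature axis.
#' @param intensities pixels-by-features matrix.
#' @param coords 0-based (x, y) integer coordinates, one row per pixel.
#' @param dim image c(width, height).
#' @param metadata optional list.
#' @rdname MSIDataCube-class
#' @export
MSIDataCube <- function(mz, intensities, coords, dim, metadata = list()) {
    storage.mode(coords) <- "integer"
    new("MSIDataCube", mz = as.numeric(mz),
        intensities = as.matrix(intensities), coords = coords,
        dim = as.integer(dim), metadata = metadata)
}

#' PeakList: picked peaks with intensity ranks
#'
#' @slot mz numeric, peak centroid m/z in Da, strictly increasing.
#' @slot intensity numeric, peak apex intensities.
#' @slot rank integer, intensity-descending rank (1 = most intense); a
#'   permutation of `seq_along(mz)`.
#'
#' @exportClass PeakList
setClass("PeakList",
    slots = c(mz = "numeric", intensity = "numeric", rank = "integer"))

setValidity("PeakList", function(object) {
    msg <- character()
    n <- length(object@mz)
    if (length(object@intensity) != n || length(object@rank) != n)
        msg <- c(msg, "mz, intensity and rank must have equal length")
    if (n > 1L && any(diff(object@mz) <= 0))
        msg <- c(msg, "peak mz must be strictly increasing")
    if (n && !identical(sort(object@rank), seq_len(n)))
        msg <- c(msg, "rank must be a permutation of 1..n")
    if (length(msg)) msg else TRUE
})

#' @param mz,intensity peak positions and apex intensities.
#' @rdname PeakList-class
#' @export
PeakList <- function(mz, intensity) {
    o <- order(mz)
    mz <- as.numeric(mz)[o]
    intensity <- as.numeric(intensity)[o]
    # ties in intensity rank: lower m/z ranks first
    rank <- integer(length(mz))
    rank[order(-intensity, mz)] <- seq_along(mz)
    new("PeakList", mz = mz, intensity = intensity, rank = rank)
}

#' SegmentationResult: embedding plus cluster labels
#'
#' @slot embedding numeric matrix (items x d), possibly 0-column when no
#'   embedding was computed.
#' @slot labels integer cluster ids in 1..k.
#' @slot k integer, number of clusters.
#' @slot wcss numeric, within-cluster sum of squares of the chosen fit; when
#'   a k sweep was run, the per-k curve is in `wcssCurve`.
#' @slot wcssCurve named numeric, WCSS per candidate k (may be empty).
#' @slot metric character, dissimilarity used ("euclidean", "cosine",
#'   "correlation").
#' @slot seed integer random seed used.
#'
#' @exportClass SegmentationResult
setClass("SegmentationResult",
    slots = c(embedding = "matrix", labels = "integer", k = "integer",
              wcss = "numeric", wcssCurve = "numeric", metric = "character",
              seed = "integer"))

setValidity("SegmentationResult", function(object) {
    msg <- character()
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > object@k))
        msg <- c(msg, "cluster labels must lie in 1..k")
    if (nrow(object@embedding) && length(object@labels) &&
        nrow(object@embedding) != length(object@labels))
        msg <- c(msg, "one label per embedded item required")
    if (length(msg)) msg else TRUE
})

#' ClassifierReport: patient-level classification performance
#'
#' Produced by [evaluateClassifier()] / [runClinicalPipeline()]. Metrics obey
#' `fpr == 1 - tnr` and `balanced_accuracy == (tpr + tnr) / 2` exactly.
#'
#' @slot selectedFeatures character vector of retained feature names (may be
#'   empty when no refinement was run).
#' @slot spectrumPredictions data.frame: spectrum id, patient id, truth,
#'   predicted label, fold.
#' @slot patientPredictions data.frame: patient id, truth, majority-vote label.
#' @slot confusion named numeric: TP, FN, TN, FP patient counts.
#' @slot metrics named numeric: tpr, tnr, fpr, balanced_accuracy.
#' @slot positiveClass character, label treated as positive.
#'
#' @exportClass ClassifierReport
setClass("ClassifierReport",
    slots = c(selectedFeatures = "character",
              spectrumPredictions = "data.frame",
              patientPredictions = "data.frame",
              confusion = "numeric", metrics = "numeric",
              positiveClass = "character"))

setValidity("ClassifierReport", function(object) {
    msg <- character()
    need <- c("TP", "FN", "TN", "FP")
    if (!all(need %in% names(object@confusion)))
        msg <- c(msg, "confusion must contain TP, FN, TN, FP")
    needm <- c("tpr", "tnr", "fpr", "balanced_accuracy")
    if (!all(needm %in% names(object@metrics)))
        msg <- c(msg, "metrics must contain tpr, tnr, fpr, balanced_accuracy")
    if (length(msg)) msg else TRUE
})
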