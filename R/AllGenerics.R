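#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: `mz()` (feature
#' axis), `intensities()` (intensity matrix or vector), `sampleData()`
#' (per-spectrum metadata), `coords()` (pixel coordinates),
#' `clusterLabels()` (segmentation labels) and `classifierMetrics()`.
#'
#' @param object a MetaboStrat S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("massWindow", function(object) standardGeneric("massWindow"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("embedding", function(object) standardGeneric("embedding"))

#' @rdname accessors
#' @export
setGeneric("classifierMetrics",
    function(object) standardGeneric("classifierMetrics"))

#' @rdname accessors
#' @export
setGeneric("peakRank", function(object) standardGeneric("peakRank"))

#' @rdname accessors
#' @export
setMethod("mz", "MassSpectrum", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("mz", "SpectrumCohort", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("mz", "MSIDataCube", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("mz", "PeakList", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("intensities", "MassSpectrum", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("intensities", "SpectrumCohort", function(object) object@intensities)

#' @rdname accessors
#' @export
setMethod("intensities", "MSIDataCube", function(object) object@intensities)

#' @rdname accessors
#' @export
setMethod("intensities", "PeakList", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("sampleData", "SpectrumCohort", function(object) object@sampleData)

#' @rdname accessors
#' @export
setMethod("coords", "MSIDataCube", function(object) object@coords)

#' @rdname accessors
#' @export
setMethod("massWindow", "SpectrumCohort", function(object) object@massWindow)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "SegmentationResult", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("embedding", "SegmentationResult", function(object) object@embedding)

#' @rdname accessors
#' @export
setMethod("classifierMetrics", "ClassifierReport",
    function(object) object@metrics)

#' @rdname accessors
#' @export
setMethod("peakRank", "PeakList", function(object) object@rank)

#' @describeIn MSIDataCube-class image grid c(width, height)
#' @export
setMethod("dim", "MSIDataCube", function(x) x@dim)

#' @describeIn MassSpectrum-class number of points
#' @param x object
#' @export
setMethod("length", "MassSpectrum", function(x) length(x@mz))

#' @describeIn PeakList-class number of peaks
#' @param x object
#' @export
setMethod("length", "PeakList", function(x) length(x@mz))

setMethod("show", "MassSpectrum", function(object) {
    cat("MassSpectrum:", length(object@mz), "points")
    if (length(object@mz))
        cat(sprintf(", m/z %.4f-%.4f", min(object@mz), max(object@mz)))
    cat("\n")
    if (length(object@meta))
        cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "SpectrumCohort", function(object) {
    cat(sprintf("SpectrumCohort: %d spectra x %d m/z bins\n",
                nrow(object@intensities), length(object@mz)))
    cat(sprintf("  mass window: %.3f-%.3f Da\n",
                object@massWindow[1L], object@massWindow[2L]))
    if ("group" %in% colnames(object@sampleData)) {
        tab <- table(object@sampleData$group)
        cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab),
                               collapse = ", "), "\n")
    }
})

setMethod("show", "MSIDataCube", function(object) {
    cat(sprintf("MSIDataCube: %d x %d pixels (%d occupied), %d features\n",
                object@dim[1L], object@dim[2L], nrow(object@intensities),
                length(object@mz)))
})

setMethod("show", "PeakList", function(object) {
    cat(sprintf("PeakList: %d peaks", length(object@mz)))
    if (length(object@mz))
        cat(sprintf(", m/z %.4f-%.4f", min(object@mz), max(object@mz)))
    cat("\n")
})

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf("SegmentationResult: %d items, k = %d (%s metric)\n",
                length(object@labels), object@k, object@metric))
    if (length(object@labels))
        cat("  cluster sizes:", paste(table(object@labels), collapse = ", "),
            "\n")
})

setMethod("show", "ClassifierReport", function(object) {
    m <- object@metrics
    cat("ClassifierReport (positive class:", object@positiveClass, ")\n")
    cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n",
                object@confusion["TP"], object@confusion["FN"],
                object@confusion["TN"], object@confusion["FP"]))
    cat(sprintf("  TPR %.3f  TNR %.3f  FPR %.3f  balanced accuracy %.3f\n",
                m["tpr"], m["tnr"], m["fpr"], m["balanced_accuracy"]))
    if (length(object@selectedFeatures))
        cat("  selected features:", length(object@selectedFeatures), "\n")
})
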