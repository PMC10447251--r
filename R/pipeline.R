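# End-to-end pipelines composing the preprocessing, segmentation,
# differential, annotation and classification stages, with reproducibility
# manifests. Each run is a pure function of its inputs and seeds; rerunning
# with the same configuration yields byte-identical outputs.

.writeTSV <- function(df, dir, name) {
    if (is.null(dir)) return(invisible(NULL))
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

.writeManifest <- function(dir, config, seeds) {
    if (is.null(dir)) return(invisible(NULL))
    manifest <- list(package = "MetaboStrat",
                     version = as.character(utils::packageVersion("MetaboStrat")),
                     config = config, seeds = seeds)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors the [msThresholds()] fields plus `mode`, `seed` and
#' optional paths; unknown fields are passed through untouched.
#'
#' @param path YAML file.
#' @return named list with an `msThresholds` element built from the
#'   threshold-like fields.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    .assert(!is.null(cfg$mode), "config must state a mode")
    thr_fields <- c("bin_width", "top_n_peaks", "fc_threshold", "p_threshold",
                    "fdr_q", "ppm_tol", "n_selected_features", "mass_window")
    args <- cfg[intersect(names(cfg), thr_fields)]
    args$mode <- cfg$mode
    cfg$thresholds <- do.call(msThresholds, args)
    if (is.null(cfg$seed)) cfg$seed <- 1L
    cfg
}

#' Run the cohort (REIMS) pipeline
#'
#' Full profile-to-annotation chain: rebin all spectra onto the common axis
#' restricted to the analysis mass window, peak-pick the mean spectrum and
#' reduce to top-N peak space, detect and drop inactive (burn-off) spectra by
#' cosine k-means (k = 2) on the peak matrix, l2-normalise, embed with cosine
#' t-SNE (3-D), cluster the embedding with Euclidean k-means (k defaults to
#' the number of group labels, mirroring one-cluster-per-genotype), run
#' pairwise volcano analysis for all group pairs, and, when a compound
#' database is supplied, annotate the discriminating ions and rank pathways.
#'
#' @param cohort a [SpectrumCohort-class] (raw profile spectra on a shared
#'   axis; typically from [generateCohort()] or [readCohort()]).
#' @param thresholds an [msThresholds()] bundle (cohort mode defaults).
#' @param k number of clusters; NULL = number of distinct active-group labels.
#' @param compound_db optional compound table for annotation.
#' @param rebin_input rebin the cohort to `thresholds$bin_width` first (set
#'   FALSE when the input is already on the analysis axis).
#' @param seed integer seed driving every stochastic stage.
#' @param output_dir optional directory to write TSV artefacts + manifest.
#' @return list: `cohort_peaks` (peak-space cohort, active spectra only),
#'   `active_mask`, `embedding`, `clusters` ([SegmentationResult-class]),
#'   `purity`, `volcano` (named list of tables), `annotation`, `pathways`.
#' @export
runCohortPipeline <- function(cohort, thresholds = msThresholds("cohort"),
                              k = NULL, compound_db = NULL,
                              rebin_input = TRUE, seed = 1L,
                              output_dir = NULL) {
    stopifnot(is(cohort, "SpectrumCohort"))
    if (!is.null(output_dir) && !dir.exists(output_dir))
        dir.create(output_dir, recursive = TRUE)

    window <- c(max(thresholds$mass_window[1], cohort@massWindow[1]),
                min(thresholds$mass_window[2], cohort@massWindow[2]))
    if (rebin_input) {
        axis <- buildMzAxis(window, thresholds$bin_width)
        mat <- t(apply(cohort@intensities, 1, function(y)
            stats::approx(cohort@mz, y, xout = axis, yleft = 0, yright = 0)$y))
        cohort <- SpectrumCohort(axis, mat, cohort@sampleData,
                                 massWindow = window)
    }

    peaks <- gradientPeakPick(meanSpectrum(cohort))
    peaks <- topNPeaks(peaks, thresholds$top_n_peaks)
    cohort_peaks <- buildDataCube(cohort, peaks)

    active <- detectActiveSpectra(cohort_peaks, seed = .childSeed(seed, "burn"))
    act_peaks <- SpectrumCohort(
        cohort_peaks@mz, cohort_peaks@intensities[active, , drop = FALSE],
        cohort_peaks@sampleData[active, , drop = FALSE],
        massWindow = cohort_peaks@massWindow)
    act_peaks <- l2Normalize(act_peaks)

    # cohort preset perplexity (30) needs n > 3 x perplexity; cap for small
    # cohorts rather than refusing to embed them
    perp <- min(30, floor((nrow(act_peaks@intensities) - 1) / 3))
    emb <- tsneEmbed(act_peaks@intensities, preset = "cohort",
                     perplexity = perp, seed = .childSeed(seed, "tsne"))
    groups <- act_peaks@sampleData$group
    if (is.null(k)) k <- length(unique(groups))
    km <- kmeansCluster(emb, k, metric = "euclidean", n_replicates = 10,
                        seed = .childSeed(seed, "kmeans"))
    seg <- new("SegmentationResult", embedding = emb,
               labels = km$labels, k = as.integer(k), wcss = km$wcss,
               wcssCurve = numeric(0), metric = "euclidean",
               seed = as.integer(seed))
    purity <- purityTable(km$labels, groups)

    volcano <- allPairsVolcano(act_peaks, thresholds = thresholds,
                               mode = "cohort")

    annotation <- pathways <- NULL
    if (!is.null(compound_db)) {
        disc <- sort(unique(unlist(lapply(volcano, function(v)
            v$mz[v$passes]))))
        annotation <- matchIons(disc, compound_db,
                                ppm_tol = thresholds$ppm_tol)
        pathways <- rankPathways(annotation)
    }

    if (!is.null(output_dir)) {
        emb_df <- data.frame(sample_id = act_peaks@sampleData$sample_id,
                             emb, cluster = km$labels)
        .writeTSV(emb_df, output_dir, "embedding.tsv")
        .writeTSV(purity, output_dir, "purity.tsv")
        for (nm in names(volcano))
            .writeTSV(volcano[[nm]], output_dir,
                      paste0("volcano_", nm, ".tsv"))
        if (!is.null(annotation))
            .writeTSV(annotation[, setdiff(colnames(annotation), "pathways")],
                      output_dir, "annotation.tsv")
        if (!is.null(pathways))
            .writeTSV(pathways[, c("pathway", "subclass", "n_unique_mz")],
                      output_dir, "pathways.tsv")
        .writeManifest(output_dir,
                       list(mode = "cohort", thresholds = unclass(thresholds),
                            k = k), list(seed = seed))
    }
    list(cohort_peaks = act_peaks, active_mask = active, embedding = emb,
         clusters = seg, purity = purity, volcano = volcano,
         annotation = annotation, pathways = pathways)
}

#' Run the MSI pipeline
#'
#' Imaging chain: peak-pick the cube's mean spectrum, keep the top-N peaks
#' (4000 by default), build the datacube, segment it with cosine k-means
#' (k = 4 by default), flag background (auto: lowest mean total intensity;
#' manual: supplied mask), optionally re-cluster tissue-only pixels
#' (background-subtracted second pass), optionally embed tissue pixels with
#' correlation-metric t-SNE, and run a pixel volcano (RMS-normalised, zeros
#' removed, q = 0.1) between two chosen label sets.
#'
#' @param cube an [MSIDataCube-class] on a dense axis (e.g. from
#'   [readImzML()] or [generateCube()]).
#' @param thresholds an [msThresholds()] bundle (msi mode defaults).
#' @param k first-pass cluster count.
#' @param second_pass_k optional tissue-only recluster count (e.g. 3).
#' @param background_mask optional manual background mask.
#' @param volcano_rois optional list `list(a = pixel indices, b = pixel
#'   indices)` defining the two regions to contrast; NULL skips the volcano.
#' @param embed run correlation-metric t-SNE on tissue pixels.
#' @param seed integer seed.
#' @param output_dir optional artefact directory.
#' @return list: `cube_peaks`, `segmentation` (from [segmentCube()]),
#'   `embedding` (or NULL), `volcano` (or NULL).
#' @export
runMSIPipeline <- function(cube, thresholds = msThresholds("msi"), k = 4,
                           second_pass_k = NULL, background_mask = NULL,
                           volcano_rois = NULL, embed = FALSE, seed = 1L,
                           output_dir = NULL) {
    stopifnot(is(cube, "MSIDataCube"))
    if (!is.null(output_dir) && !dir.exists(output_dir))
        dir.create(output_dir, recursive = TRUE)

    peaks <- gradientPeakPick(meanSpectrum(cube))
    peaks <- topNPeaks(peaks, thresholds$top_n_peaks)
    cube_peaks <- buildDataCube(cube, peaks)

    segres <- segmentCube(cube_peaks, k = k, metric = "cosine",
                          background_mask = background_mask,
                          second_pass_k = second_pass_k,
                          seed = .childSeed(seed, "segment"))

    emb <- NULL
    if (embed) {
        idx <- which(!segres$background)
        emb <- tsneEmbed(cube_peaks@intensities[idx, , drop = FALSE],
                         preset = "msi", seed = .childSeed(seed, "tsne"))
    }

    volcano <- NULL
    if (!is.null(volcano_rois)) {
        rows <- c(volcano_rois$a, volcano_rois$b)
        roi_groups <- rep(c("roi_a", "roi_b"),
                          c(length(volcano_rois$a), length(volcano_rois$b)))
        sub <- cube_peaks@intensities[rows, , drop = FALSE]
        colnames(sub) <- sprintf("%.6f", cube_peaks@mz)
        volcano <- pairwiseVolcano(sub, roi_groups, "roi_a", "roi_b",
                                   thresholds = thresholds, mode = "msi")
        volcano$mz <- cube_peaks@mz
    }

    if (!is.null(output_dir)) {
        lbl <- data.frame(x = cube_peaks@coords[, 1],
                          y = cube_peaks@coords[, 2],
                          cluster = segres$segmentation@labels,
                          background = segres$background)
        if (!is.null(segres$tissue_labels))
            lbl$tissue_cluster <- segres$tissue_labels
        .writeTSV(lbl, output_dir, "labels.tsv")
        if (!is.null(volcano)) .writeTSV(volcano, output_dir, "volcano_roi.tsv")
        .writeManifest(output_dir,
                       list(mode = "msi", thresholds = unclass(thresholds),
                            k = k, second_pass_k = second_pass_k),
                       list(seed = seed))
    }
    list(cube_peaks = cube_peaks, segmentation = segres, embedding = emb,
         volcano = volcano)
}

#' Run the clinical classification pipeline
#'
#' Replicate-aware LOPO evaluation of a clinical feature table (per-fold
#' feature refinement, linear SVM, patient-level majority vote), plus the
#' clinical-preset t-SNE of the refined feature space.
#'
#' @param features spectra x features matrix.
#' @param meta data.frame with `patient_id`, `label` (and optionally `batch`).
#' @param thresholds an [msThresholds()] bundle; `n_selected_features` sets
#'   the refined set size.
#' @param use_batch use the batch column in the confounder filter.
#' @param refine_once optimistic whole-data refinement (see [lopoEvaluate()]).
#' @param seed integer seed.
#' @param output_dir optional artefact directory.
#' @return list: `report` (a [ClassifierReport-class]), `embedding` (n x 3
#'   t-SNE of the refined features).
#' @export
runClinicalPipeline <- function(features, meta,
                                thresholds = msThresholds("clinical"),
                                use_batch = TRUE, refine_once = FALSE,
                                seed = 1L, output_dir = NULL) {
    if (!is.null(output_dir) && !dir.exists(output_dir))
        dir.create(output_dir, recursive = TRUE)
    report <- lopoEvaluate(features, meta,
                           target_k = thresholds$n_selected_features,
                           use_batch = use_batch, refine_once = refine_once,
                           seed = seed)
    sel <- report@selectedFeatures
    x_sel <- as.matrix(features)[, sel, drop = FALSE]
    emb <- visualizeRefined(x_sel, seed = .childSeed(seed, "tsne"))

    if (!is.null(output_dir)) {
        .writeTSV(report@patientPredictions, output_dir,
                  "patient_predictions.tsv")
        jsonlite::write_json(
            list(confusion = as.list(report@confusion),
                 metrics = as.list(report@metrics),
                 positive_class = report@positiveClass,
                 selected_features = report@selectedFeatures),
            file.path(output_dir, "report.json"),
            auto_unbox = TRUE, pretty = TRUE, digits = NA)
        .writeManifest(output_dir,
                       list(mode = "clinical",
                            thresholds = unclass(thresholds),
                            use_batch = use_batch,
                            refine_once = refine_once),
                       list(seed = seed))
    }
    list(report = report, embedding = emb)
}
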