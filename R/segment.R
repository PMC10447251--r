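# Unsupervised structure discovery: k-means with cosine or Euclidean
# dissimilarity, t-SNE embeddings with named presets, elbow-method model
# selection, burn-region detection for REIMS acquisitions and spatial
# segmentation of MSI datacubes.

# k-means++ seeding: first centre uniform, subsequent centres drawn with
# probability proportional to squared distance from the nearest chosen centre.
# Guarantees distinct starting centres whenever k distinct points exist.
.kmeansppInit <- function(x, k) {
    n <- nrow(x)
    centers <- matrix(NA_real_, k, ncol(x))
    idx <- sample.int(n, 1)
    centers[1, ] <- x[idx, ]
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in seq_len(k - 1)) {
        if (all(d2 == 0)) {
            # fewer distinct points than k; let stats::kmeans raise the
            # degenerate-clustering condition
            centers[j + 1, ] <- x[sample.int(n, 1), ]
            next
        }
        idx <- sample.int(n, 1, prob = d2)
        centers[j + 1, ] <- x[idx, ]
        d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
    }
    centers
}

.rowUnit <- function(x) {
    nrm <- sqrt(rowSums(x^2))
    .assert(all(nrm > 0), "cannot compute cosine geometry for all-zero rows")
    x / nrm
}

#' k-means clustering with cosine or Euclidean dissimilarity
#'
#' Cosine k-means is realised as standard k-means on unit-normalised rows
#' with Euclidean centroids (the two objectives share their optima up to the
#' monotone mapping between cosine dissimilarity and squared chord distance).
#' Each of the `n_replicates` restarts is seeded with k-means++ (probability
#' proportional to squared distance from the chosen centres, the common
#' default of modern k-means implementations) and the best restart (lowest
#' within-cluster sum of squares) is returned, deterministically for a given
#' seed.
#'
#' @param points numeric matrix, items in rows.
#' @param k number of clusters, 1 <= k <= n.
#' @param metric "euclidean" or "cosine".
#' @param n_replicates random restarts (default 10).
#' @param seed integer seed.
#' @param iter_max Lloyd/Hartigan-Wong iteration cap.
#' @return list with `labels` (integer 1..k), `wcss` (total within-cluster
#'   sum of squares in the clustering geometry), `centers`.
#' @export
kmeansCluster <- function(points, k, metric = c("euclidean", "cosine"),
                          n_replicates = 10, seed = 1L, iter_max = 100) {
    metric <- match.arg(metric)
    points <- as.matrix(points)
    n <- nrow(points)
    .assert(k >= 1 && k <= n, "k must be between 1 and the number of items (%d)", n)
    x <- if (metric == "cosine") .rowUnit(points) else points
    if (k > 1 && sum(sweep(x, 2, colMeans(x))^2) == 0)
        stop("degenerate clustering: all points identical", call. = FALSE)
    withr::with_seed(as.integer(seed), {
        if (k == 1) {
            ctr <- matrix(colMeans(x), 1)
            return(list(labels = rep(1L, n),
                        wcss = sum(sweep(x, 2, ctr[1, ])^2), centers = ctr))
        }
        if (k == n)  # every point its own cluster
            return(list(labels = seq_len(n), wcss = 0, centers = x))
        best <- NULL
        for (r in seq_len(n_replicates)) {
            ctr <- .kmeansppInit(x, k)
            fit <- tryCatch(
                suppressWarnings(
                    stats::kmeans(x, centers = ctr, iter.max = iter_max)),
                error = function(e) {
                    if (grepl("distinct|empty", conditionMessage(e)))
                        stop("degenerate clustering: fewer than k = ", k,
                             " distinct points", call. = FALSE)
                    stop(e)
                })
            if (is.null(best) || fit$tot.withinss < best$tot.withinss)
                best <- fit
        }
        list(labels = as.integer(best$cluster), wcss = best$tot.withinss,
             centers = best$centers)
    })
}

#' Elbow-method selection of the cluster number
#'
#' Runs [kmeansCluster()] over `k_range`, records the WCSS curve, and picks
#' the k of largest curvature (maximum second difference of WCSS over the
#' interior of the range); ties resolve to the smaller k. If the curve comes
#' out non-monotone (a failed fit at some k), it is recomputed once with five
#' times the replicates, with a warning.
#'
#' @param points numeric matrix, items in rows.
#' @param k_range increasing integer vector of at least 3 candidate k.
#' @param metric "euclidean" or "cosine".
#' @param n_replicates restarts per k.
#' @param seed integer seed.
#' @return list with `k` (selected), `wcss_curve` (named by k).
#' @export
elbowSelectK <- function(points, k_range = 1:8,
                         metric = c("euclidean", "cosine"),
                         n_replicates = 10, seed = 1L) {
    metric <- match.arg(metric)
    k_range <- sort(as.integer(k_range))
    .assert(length(k_range) >= 3, "k_range must contain at least 3 values")
    sweep_wcss <- function(reps) vapply(k_range, function(k)
        kmeansCluster(points, k, metric, reps,
                      seed = .childSeed(seed, paste0("elbow", k)))$wcss,
        numeric(1))
    wcss <- sweep_wcss(n_replicates)
    if (any(diff(wcss) > 1e-8)) {
        warning("non-monotone WCSS curve; recomputing with more replicates")
        wcss <- sweep_wcss(5 * n_replicates)
    }
    names(wcss) <- k_range
    list(k = selectElbow(wcss, k_range), wcss_curve = wcss)
}

#' Elbow rule on a WCSS curve
#'
#' Given within-cluster sum of squares per candidate k, returns the interior
#' k with the largest curvature (second difference of the curve); ties (and
#' a perfectly linear curve) resolve to the smallest interior k.
#'
#' @param wcss numeric WCSS values along `k_range`.
#' @param k_range increasing integer vector, same length as `wcss`.
#' @return the selected k.
#' @export
selectElbow <- function(wcss, k_range = seq_along(wcss)) {
    .assert(length(wcss) == length(k_range) && length(wcss) >= 3,
            "need WCSS for at least 3 candidate k")
    interior <- 2:(length(k_range) - 1)
    curvature <- wcss[interior - 1] - 2 * wcss[interior] + wcss[interior + 1]
    k_range[interior[which.max(curvature)]]  # which.max: first hit = smallest k
}

#' Detect active (tissue-contact) spectra in a REIMS acquisition
#'
#' Clusters the raw spectra with cosine k-means, k = 2, and marks the cluster
#' with the higher mean total ion current as active; the other cluster holds
#' the inactive (forceps-off) segments that are removed before analysis.
#'
#' @param cohort a [SpectrumCohort-class] with >= 2 spectra.
#' @param n_replicates,seed passed to [kmeansCluster()]; the default of 50
#'   restarts makes the small inactive cluster reliably found even when the
#'   active spectra carry strong group structure of their own.
#' @return logical mask, TRUE for active spectra.
#' @export
detectActiveSpectra <- function(cohort, n_replicates = 50, seed = 1L) {
    stopifnot(is(cohort, "SpectrumCohort"))
    m <- cohort@intensities
    .assert(nrow(m) >= 2, "need at least 2 spectra")
    fit <- kmeansCluster(m, 2, metric = "cosine",
                         n_replicates = n_replicates, seed = seed)
    tic <- rowSums(m)
    active_cluster <- which.max(tapply(tic, fit$labels, mean))
    fit$labels == as.integer(names(active_cluster))
}

.pairwiseDist <- function(x, metric) {
    if (metric == "cosine") {
        u <- .rowUnit(x)
        d <- 1 - tcrossprod(u)
    } else if (metric == "correlation") {
        d <- 1 - stats::cor(t(x))
    } else {
        return(stats::dist(x))
    }
    d[d < 0] <- 0
    stats::as.dist(d)
}

#' t-SNE embedding with named presets
#'
#' Reduces an items-by-features matrix to `dims` dimensions with t-SNE.
#' Three presets bundle the settings used for each data type:
#' \describe{
#'   \item{`cohort`}{cosine distance, perplexity 30, random initialisation —
#'     the REIMS cohort setting ("default hyperparameters" of the original
#'     tooling, mapped to portable values).}
#'   \item{`msi`}{correlation distance, perplexity 30, random init.}
#'   \item{`clinical`}{Euclidean distance, perplexity 5, learning rate 50,
#'     PCA initialisation — the empirically tuned clinical setting.}
#' }
#' Explicit arguments override the preset. Exact (theta = 0) gradients are
#' used so results depend only on the seed, not on tree approximations.
#'
#' @param x numeric matrix, items in rows (n > 3 x perplexity required).
#' @param preset "cohort", "msi" or "clinical".
#' @param metric "cosine", "correlation" or "euclidean".
#' @param dims embedding dimensionality (default 3).
#' @param perplexity,learning_rate t-SNE hyperparameters.
#' @param init "random" or "pca".
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @return numeric matrix n x dims.
#' @export
tsneEmbed <- function(x, preset = c("cohort", "msi", "clinical"),
                      metric = NULL, dims = 3, perplexity = NULL,
                      learning_rate = NULL, init = NULL, seed = 1L,
                      max_iter = 500) {
    preset <- match.arg(preset)
    defaults <- switch(preset,
        cohort = list(metric = "cosine", perplexity = 30,
                      learning_rate = 200, init = "random"),
        msi = list(metric = "correlation", perplexity = 30,
                   learning_rate = 200, init = "random"),
        clinical = list(metric = "euclidean", perplexity = 5,
                        learning_rate = 50, init = "pca"))
    metric <- if (is.null(metric)) defaults$metric else
        match.arg(metric, c("cosine", "correlation", "euclidean"))
    if (is.null(perplexity)) perplexity <- defaults$perplexity
    if (is.null(learning_rate)) learning_rate <- defaults$learning_rate
    init <- if (is.null(init)) defaults$init else
        match.arg(init, c("random", "pca"))
    x <- as.matrix(x)
    n <- nrow(x)
    .assert(ncol(x) >= 2, "need at least 2 features")
    .assert(n - 1 >= 3 * perplexity,
            "perplexity %.1f too large for %d items (need n - 1 >= 3 x perplexity)",
            perplexity, n)
    d <- .pairwiseDist(x, metric)
    withr::with_seed(as.integer(seed), {
        y_init <- NULL
        if (init == "pca") {
            pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
            sc <- pc$x[, seq_len(min(dims, ncol(pc$x))), drop = FALSE]
            if (ncol(sc) < dims)
                sc <- cbind(sc, matrix(0, n, dims - ncol(sc)))
            y_init <- sc / stats::sd(sc[, 1]) * 1e-4
        }
        fit <- Rtsne::Rtsne(d, dims = dims, perplexity = perplexity,
                            eta = learning_rate, theta = 0,
                            is_distance = TRUE, Y_init = y_init,
                            max_iter = max_iter, verbose = FALSE,
                            check_duplicates = FALSE)
        fit$Y
    })
}

#' Spatial segmentation of an MSI datacube
#'
#' Clusters pixel spectra with k-means (cosine metric by default, mirroring
#' the imaging workflow), identifies background, and optionally re-clusters
#' the tissue-only pixels in a second pass ("background-subtracted"
#' segmentation). Background is taken from a user-supplied logical mask
#' (manual mode, taking precedence) or, in auto mode, as the cluster with the
#' lowest mean total intensity.
#'
#' @param cube an [MSIDataCube-class] in peak space.
#' @param k number of clusters for the first pass (default 4).
#' @param metric passed to [kmeansCluster()].
#' @param background_mask optional logical vector (length = pixels), TRUE for
#'   background; overrides auto-detection.
#' @param second_pass_k optional k for re-clustering tissue pixels after
#'   background removal (e.g. 3); NULL skips the second pass.
#' @param n_replicates,seed passed to [kmeansCluster()].
#' @return list with `segmentation` (a [SegmentationResult-class] over all
#'   pixels), `background` (logical mask), `tissue_labels` (integer labels on
#'   tissue pixels from the second pass, NA elsewhere; NULL if no second
#'   pass).
#' @export
segmentCube <- function(cube, k = 4, metric = c("cosine", "euclidean"),
                        background_mask = NULL, second_pass_k = NULL,
                        n_replicates = 10, seed = 1L) {
    stopifnot(is(cube, "MSIDataCube"))
    metric <- match.arg(metric)
    m <- cube@intensities
    fit <- kmeansCluster(m, k, metric = metric, n_replicates = n_replicates,
                         seed = seed)
    if (!is.null(background_mask)) {
        .assert(length(background_mask) == nrow(m),
                "background mask length (%d) does not match pixel count (%d)",
                length(background_mask), nrow(m))
        bg <- as.logical(background_mask)
    } else {
        tic <- rowSums(m)
        mean_tic <- tapply(tic, fit$labels, mean)
        bg_cluster <- as.integer(names(which.min(mean_tic)))
        bg <- fit$labels == bg_cluster
    }
    seg <- new("SegmentationResult", embedding = matrix(numeric(0), 0, 0),
               labels = fit$labels, k = as.integer(k), wcss = fit$wcss,
               wcssCurve = numeric(0), metric = metric,
               seed = as.integer(seed))
    tissue_labels <- NULL
    if (!is.null(second_pass_k)) {
        idx <- which(!bg)
        .assert(length(idx) >= second_pass_k,
                "fewer tissue pixels than second-pass clusters")
        fit2 <- kmeansCluster(m[idx, , drop = FALSE], second_pass_k,
                              metric = metric, n_replicates = n_replicates,
                              seed = .childSeed(seed, "second_pass"))
        tissue_labels <- rep(NA_integer_, nrow(m))
        tissue_labels[idx] <- fit2$labels
    }
    list(segmentation = seg, background = bg, tissue_labels = tissue_labels)
}

#' Cluster-by-group purity table
#'
#' Cross-tabulates cluster labels against a grouping factor and reports,
#' for every (cluster, group) cell, the spectrum count and the percentage of
#' that group's spectra falling in the cluster (percentages per group sum to
#' 100).
#'
#' @param labels cluster labels.
#' @param groups group labels, same length.
#' @return data.frame with columns `cluster`, `group`, `count`,
#'   `pct_of_group`.
#' @export
purityTable <- function(labels, groups) {
    .assert(length(labels) == length(groups),
            "labels and groups must be aligned")
    tab <- table(cluster = labels, group = groups)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    colnames(df) <- c("cluster", "group", "count")
    totals <- stats::ave(df$count, df$group, FUN = sum)
    df$pct_of_group <- 100 * df$count / totals
    df[order(df$cluster, df$group), , drop = FALSE]
}
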