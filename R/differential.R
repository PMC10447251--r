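# Pairwise differential-ion (volcano) analysis with BH-FDR control.

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (q-values): sort ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and return in the input
#' order. NAs (untestable features) are passed through and do not count
#' towards m.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return numeric vector of q-values.
#' @export
bhAdjust <- function(p) {
    .assert(is.numeric(p), "p must be numeric")
    .assert(all(p >= 0 & p <= 1, na.rm = TRUE),
            "p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Root-mean-square normalisation of pixel spectra
#'
#' Divides every row by the root mean square of its intensities, the
#' normalisation applied to pixel data before region-of-interest volcano
#' analysis. Idempotent. A zero row cannot be normalised and raises an error
#' naming the pixel.
#'
#' @param x numeric matrix, pixels in rows.
#' @return matrix with unit-RMS rows.
#' @export
rmsNormalize <- function(x) {
    x <- as.matrix(x)
    rms <- sqrt(rowMeans(x^2))
    if (any(rms == 0)) {
        bad <- which(rms == 0)
        ids <- if (!is.null(rownames(x))) rownames(x)[bad] else bad
        stop("cannot RMS-normalize all-zero pixels: ",
             paste(ids, collapse = ", "), call. = FALSE)
    }
    x / rms
}

# Vectorised two-sample t-tests over matrix columns. Returns p-values (NA
# where the test is undefined) and the statistics used.
.colTTest <- function(a, b, var_equal = TRUE) {
    na <- nrow(a); nb <- nrow(b)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
    if (var_equal) {
        sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
        se <- sqrt(sp2 * (1 / na + 1 / nb))
        df <- rep(na + nb - 2, length(ma))
    } else {
        se <- sqrt(va / na + vb / nb)
        df <- (va / na + vb / nb)^2 /
            ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    tt <- (ma - mb) / se
    p <- 2 * stats::pt(-abs(tt), df)
    p[!is.finite(tt)] <- NA
    list(p = p, t = tt, mean_a = ma, mean_b = mb, var_a = va, var_b = vb)
}

#' Pairwise volcano analysis between two groups
#'
#' Per feature: log2 fold change of group mean intensities, a two-sided
#' two-sample t-test (pooled-variance Student by default, Welch via
#' `var_equal = FALSE`), BH adjustment across all testable features, and the
#' volcano pass flag `|FC| > fc_threshold & p < p_threshold & q <= fdr_q`.
#'
#' In `mode = "msi"` the rows are pixels: each pixel spectrum is first RMS
#' normalised and, per feature, zero intensities are dropped from that
#' feature's test (zeros are missing signal in imaging data). In
#' `mode = "cohort"` the matrix is used as supplied (the cohort pipeline
#' l2-normalises upstream).
#'
#' Features with fewer than 2 usable values in a group, or zero variance in
#' both groups, are untestable: they get NA p/q, `tested = FALSE`, and are
#' excluded from the BH family.
#'
#' @param x a [SpectrumCohort-class] or numeric matrix (items x features).
#' @param groups group label per row (taken from `sampleData(x)$group` when
#'   `x` is a cohort and `groups` is NULL).
#' @param group_a,group_b the two labels to contrast (a over b).
#' @param thresholds an [msThresholds()] bundle.
#' @param mode "cohort" or "msi".
#' @param var_equal pooled-variance t-test when TRUE (default), Welch when
#'   FALSE.
#' @return data.frame: `mz` (feature axis or column index), `log2_fc`,
#'   `p_value`, `q_value`, `tested`, `passes`.
#' @export
pairwiseVolcano <- function(x, groups = NULL, group_a, group_b,
                            thresholds = msThresholds(),
                            mode = c("cohort", "msi"), var_equal = TRUE) {
    mode <- match.arg(mode)
    if (is(x, "SpectrumCohort")) {
        if (is.null(groups)) groups <- x@sampleData$group
        feat_mz <- x@mz
        m <- x@intensities
    } else {
        m <- as.matrix(x)
        feat_mz <- if (!is.null(colnames(m)))
            suppressWarnings(as.numeric(colnames(m))) else rep(NA_real_, ncol(m))
        if (anyNA(feat_mz)) feat_mz <- seq_len(ncol(m))
    }
    .assert(!is.null(groups) && length(groups) == nrow(m),
            "groups must label every row")
    ia <- which(groups == group_a)
    ib <- which(groups == group_b)
    .assert(length(ia) >= 2 && length(ib) >= 2,
            "both groups need at least 2 items (got %d and %d)",
            length(ia), length(ib))
    if (mode == "msi") m <- rmsNormalize(m)
    a <- m[ia, , drop = FALSE]
    b <- m[ib, , drop = FALSE]

    if (mode == "msi") {
        # per-feature zero removal
        nfeat <- ncol(m)
        p <- rep(NA_real_, nfeat)
        mean_a <- mean_b <- rep(NA_real_, nfeat)
        for (j in seq_len(nfeat)) {
            aj <- a[a[, j] > 0, j]
            bj <- b[b[, j] > 0, j]
            if (length(aj) < 2 || length(bj) < 2) next
            if (stats::var(aj) == 0 && stats::var(bj) == 0) {
                mean_a[j] <- mean(aj); mean_b[j] <- mean(bj)
                next
            }
            r <- .colTTest(matrix(aj), matrix(bj), var_equal)
            p[j] <- r$p
            mean_a[j] <- mean(aj); mean_b[j] <- mean(bj)
        }
    } else {
        r <- .colTTest(a, b, var_equal)
        p <- r$p
        p[r$var_a == 0 & r$var_b == 0] <- NA
        mean_a <- r$mean_a; mean_b <- r$mean_b
    }

    log2_fc <- log2(mean_a / mean_b)
    log2_fc[which(mean_a == mean_b)] <- 0  # covers 0/0 of identical groups
    tested <- !is.na(p)
    q <- rep(NA_real_, length(p))
    q[tested] <- bhAdjust(p[tested])
    passes <- tested &
        abs(log2_fc) > log2(thresholds$fc_threshold) &
        p < thresholds$p_threshold & q <= thresholds$fdr_q
    passes[is.na(passes)] <- FALSE
    data.frame(mz = feat_mz, log2_fc = log2_fc, p_value = p, q_value = q,
               tested = tested, passes = passes)
}

#' Volcano analysis for every group pair
#'
#' Convenience wrapper running [pairwiseVolcano()] for all unordered group
#' pairs of a cohort.
#'
#' @inheritParams pairwiseVolcano
#' @return named list of volcano data.frames, names `"A_vs_B"`.
#' @export
allPairsVolcano <- function(x, groups = NULL, thresholds = msThresholds(),
                            mode = c("cohort", "msi"), var_equal = TRUE) {
    mode <- match.arg(mode)
    if (is(x, "SpectrumCohort") && is.null(groups))
        groups <- x@sampleData$group
    gl <- unique(groups)
    .assert(length(gl) >= 2, "need at least two groups")
    out <- list()
    for (i in seq_len(length(gl) - 1)) for (j in (i + 1):length(gl)) {
        nm <- paste0(gl[i], "_vs_", gl[j])
        out[[nm]] <- pairwiseVolcano(x, groups, gl[i], gl[j], thresholds,
                                     mode, var_equal)
    }
    out
}
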