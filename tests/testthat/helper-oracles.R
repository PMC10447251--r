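# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# step-up FDR adjustment straight from the definition
bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m))
        q[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
    q
}

# all-pairs ppm match scan
match_oracle <- function(queries, masses, names, shifts, adduct_names, tol) {
    hits <- list()
    for (q in queries) for (ai in seq_along(shifts)) for (ci in seq_along(masses)) {
        theo <- masses[ci] + shifts[ai]
        ppm <- (q - theo) / theo * 1e6
        if (abs(ppm) <= tol)
            hits[[length(hits) + 1]] <- data.frame(
                query_mz = q, adduct = adduct_names[ai],
                compound_name = names[ci], ppm_error = ppm)
    }
    if (!length(hits)) return(NULL)
    do.call(rbind, hits)
}

# exhaustive local-maximum scan (assumes no ties in y)
localmax_oracle <- function(y) {
    n <- length(y)
    which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}

# minimum 2-cluster WCSS over all bipartitions (n <= 16)
exhaustive_kmeans2 <- function(x) {
    n <- nrow(x)
    best <- Inf
    css <- function(rows) {
        if (length(rows) == 0) return(0)
        sum(scale(x[rows, , drop = FALSE], scale = FALSE)^2)
    }
    for (m in seq_len(2^(n - 1) - 1)) {
        a <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
        b <- setdiff(seq_len(n), a)
        best <- min(best, css(a) + css(b))
    }
    best
}

# patient-ids permuted among patients, replicate structure kept
permute_patient_labels <- function(meta, seed) {
    withr::with_seed(seed, {
        pat <- sort(unique(meta$patient_id))
        lab <- tapply(meta$label, meta$patient_id, `[`, 1)[pat]
        new_lab <- sample(lab)
        meta$label <- new_lab[match(meta$patient_id, pat)]
        meta
    })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
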