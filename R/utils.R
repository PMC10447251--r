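.assert <- function(cond, ...) {
    if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' Analysis thresholds
#'
#' Bundles the tunable cut-offs used across the pipeline. Defaults follow the
#' published REIMS/MSI settings: 0.001 Da rebinning, top 2000 (cohort) or 4000
#' (MSI) peaks, volcano filter |FC| > 1.5 with p < 0.05 and BH q <= 0.05
#' (cohort) or 0.1 (MSI), 5 ppm annotation tolerance, 50 refined classifier
#' features, and per-mode mass windows (m/z 600-1500 cohort REIMS, 50-1200
#' clinical).
#'
#' @param mode one of "cohort", "msi", "clinical"; selects mode defaults.
#' @param bin_width rebinning bin width in Da.
#' @param top_n_peaks number of peaks kept after picking.
#' @param fc_threshold fold-change cut-off (ratio scale, > 1).
#' @param p_threshold two-sided p-value cut-off.
#' @param fdr_q BH false-discovery-rate cut-off.
#' @param ppm_tol annotation mass tolerance in ppm.
#' @param n_selected_features refined feature-set size for classification.
#' @param mass_window analysis mass window c(lower, upper) in Da.
#'
#' @return a list with class "msThresholds".
#' @export
msThresholds <- function(mode = c("cohort", "msi", "clinical"),
                         bin_width = 0.001,
                         top_n_peaks = NULL,
                         fc_threshold = 1.5,
                         p_threshold = 0.05,
                         fdr_q = NULL,
                         ppm_tol = 5,
                         n_selected_features = 50,
                         mass_window = NULL) {
    mode <- match.arg(mode)
    if (is.null(top_n_peaks))
        top_n_peaks <- if (mode == "msi") 4000L else 2000L
    if (is.null(fdr_q)) fdr_q <- if (mode == "msi") 0.1 else 0.05
    if (is.null(mass_window))
        mass_window <- switch(mode, cohort = c(600, 1500),
                              msi = c(50, 1200), clinical = c(50, 1200))
    .assert(bin_width > 0, "bin_width must be positive")
    .assert(top_n_peaks >= 1, "top_n_peaks must be >= 1")
    .assert(fc_threshold > 0, "fc_threshold must be positive")
    .assert(p_threshold > 0 && p_threshold < 1,
            "p_threshold must be in (0,1)")
    .assert(fdr_q > 0 && fdr_q < 1, "fdr_q must be in (0,1)")
    .assert(ppm_tol > 0, "ppm_tol must be positive")
    .assert(n_selected_features >= 1, "n_selected_features must be >= 1")
    .assert(length(mass_window) == 2 && mass_window[1] < mass_window[2],
            "mass_window must be c(lower, upper) with lower < upper")
    structure(list(mode = mode, bin_width = bin_width,
                   top_n_peaks = as.integer(top_n_peaks),
                   fc_threshold = fc_threshold, p_threshold = p_threshold,
                   fdr_q = fdr_q, ppm_tol = ppm_tol,
                   n_selected_features = as.integer(n_selected_features),
                   mass_window = as.numeric(mass_window)),
              class = "msThresholds")
}

# Derive a child seed from a base seed and a stage tag, staying within 32-bit
# integer range. Deterministic and cheap; avoids reusing one seed across
# unrelated stochastic stages.
.childSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
    as.integer((as.numeric(seed) * 10007 + h) %% .Machine$integer.max)
}
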