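# Synthetic-data generators with planted ground truth.
#
# Every generator is a pure function of its spec plus seed: identical calls
# give bit-identical output, and no global RNG state leaks (withr::with_seed).

#' Specification of a synthetic spectral cohort
#'
#' Describes a multi-group REIMS-style cohort: per-group sample counts,
#' technical replicates, ion count and placement window, a group-by-ion
#' multiplicative effect matrix, multiplicative log-normal intensity noise,
#' and a fraction of "inactive" acquisition segments (near-zero spectra that
#' stand in for periods when the sampling forceps are off tissue).
#'
#' The default design mirrors a five-genotype intestinal cohort (WT, KRAS,
#' APC, APC KRAS, APC KRAS PTEN with 3/4/11/4/5 animals) with four technical
#' replicate spectra per animal, a 4-fold boost on `ions_per_group`
#' group-specific ions, log-normal noise sigma 0.2 and 10% inactive segments.
#'
#' @param n_groups number of groups.
#' @param samples_per_group integer vector (recycled) of samples per group.
#' @param spectra_per_sample technical replicates per sample.
#' @param n_ions number of ions placed in the window.
#' @param mz_range ion placement window c(lower, upper) in Da.
#' @param effect_matrix n_groups x n_ions matrix of non-negative
#'   multiplicative effects; NULL builds a block design giving each group
#'   `ions_per_group` private ions boosted by `effect_size`.
#' @param ions_per_group,effect_size block-design parameters used when
#'   `effect_matrix` is NULL.
#' @param noise_sigma log-scale standard deviation of intensity noise.
#' @param background_fraction fraction in [0, 1) of inactive spectra.
#' @param peak_fwhm Gaussian peak full width at half maximum, in Da at m/z
#'   600 (scales linearly with m/z).
#' @param axis_step sampling step of the rendered profile axis, Da.
#' @param baseline_noise amplitude of additive uniform baseline noise
#'   (0 disables it).
#' @param group_names optional group label vector.
#' @param seed integer seed.
#'
#' @return a list with class "cohortSpec".
#' @export
cohortSpec <- function(n_groups = 5,
                       samples_per_group = c(3, 4, 11, 4, 5),
                       spectra_per_sample = 4,
                       n_ions = 200,
                       mz_range = c(600, 1000),
                       effect_matrix = NULL,
                       ions_per_group = 10,
                       effect_size = 4,
                       noise_sigma = 0.2,
                       background_fraction = 0.1,
                       peak_fwhm = 0.05,
                       axis_step = 0.01,
                       baseline_noise = 0,
                       group_names = NULL,
                       seed = 1L) {
    n_groups <- as.integer(n_groups)
    samples_per_group <- rep_len(as.integer(samples_per_group), n_groups)
    if (is.null(effect_matrix)) {
        .assert(ions_per_group * n_groups <= n_ions,
                "not enough ions for %d private ions per group", ions_per_group)
        effect_matrix <- matrix(1, n_groups, n_ions)
        for (g in seq_len(n_groups)) {
            idx <- (g - 1L) * ions_per_group + seq_len(ions_per_group)
            effect_matrix[g, idx] <- effect_size
        }
    }
    effect_matrix <- as.matrix(effect_matrix)
    .assert(nrow(effect_matrix) == n_groups && ncol(effect_matrix) == n_ions,
            "effect_matrix must be n_groups (%d) x n_ions (%d), got %d x %d",
            n_groups, n_ions, nrow(effect_matrix), ncol(effect_matrix))
    .assert(all(effect_matrix >= 0), "effects must be non-negative")
    .assert(mz_range[1] < mz_range[2], "mz_range lower must be < upper")
    .assert(background_fraction >= 0 && background_fraction < 1,
            "background_fraction must be in [0, 1)")
    .assert(noise_sigma >= 0, "noise_sigma must be non-negative")
    if (is.null(group_names))
        group_names <- if (n_groups == 5)
            c("WT", "KRAS", "APC", "APC_KRAS", "APC_KRAS_PTEN") else
            sprintf("group%d", seq_len(n_groups))
    structure(list(n_groups = n_groups, samples_per_group = samples_per_group,
                   spectra_per_sample = as.integer(spectra_per_sample),
                   n_ions = as.integer(n_ions), mz_range = as.numeric(mz_range),
                   effect_matrix = effect_matrix, noise_sigma = noise_sigma,
                   background_fraction = background_fraction,
                   peak_fwhm = peak_fwhm, axis_step = axis_step,
                   baseline_noise = baseline_noise,
                   group_names = rep_len(group_names, n_groups),
                   seed = as.integer(seed)),
              class = "cohortSpec")
}

#' Generate a synthetic spectral cohort
#'
#' Draws ion positions uniformly in the spec's window, per-ion baseline
#' intensities log-uniform in [50, 500], and renders each spectrum as a sum
#' of Gaussian profiles with intensity
#' `baseline x group effect x lognormal(0, noise_sigma)`. A
#' `background_fraction` of spectra are scaled by 0.01 to emulate inactive
#' (forceps-off) acquisition segments; their planted activity status is in
#' `sampleData(cohort)$active`.
#'
#' @param spec a [cohortSpec()].
#' @param render "profile" renders dense Gaussian-peak spectra on a uniform
#'   axis; "peaks" returns the ion-level intensity matrix directly (columns =
#'   ion centroids), convenient for statistical calibration at scale.
#'
#' @return a [SpectrumCohort-class]; planted truth is in `sampleData()`
#'   (columns `group`, `active`, `sex`) and in `attr(cohort, "ion_mz")` /
#'   `attr(cohort, "effect_matrix")`.
#' @export
generateCohort <- function(spec, render = c("profile", "peaks")) {
    stopifnot(inherits(spec, "cohortSpec"))
    render <- match.arg(render)
    withr::with_seed(spec$seed, {
        ion_mz <- sort(stats::runif(spec$n_ions, spec$mz_range[1] + 1,
                                    spec$mz_range[2] - 1))
        baseline <- exp(stats::runif(spec$n_ions, log(50), log(500)))

        groups <- rep(spec$group_names, times = spec$samples_per_group)
        n_samples <- length(groups)
        sample_id <- sprintf("S%03d", seq_len(n_samples))
        sex <- rep_len(c("M", "F"), n_samples)[sample(n_samples)]

        rows <- expand.grid(rep = seq_len(spec$spectra_per_sample),
                            sample = seq_len(n_samples))
        n_spectra <- nrow(rows)
        n_bg <- round(spec$background_fraction * n_spectra /
                      max(1e-9, 1 - spec$background_fraction))
        active <- c(rep(TRUE, n_spectra), rep(FALSE, n_bg))

        g_idx <- match(groups[rows$sample], spec$group_names)
        ion_int <- matrix(0, n_spectra + n_bg, spec$n_ions)
        for (i in seq_len(n_spectra)) {
            noise <- if (spec$noise_sigma > 0)
                stats::rlnorm(spec$n_ions, 0, spec$noise_sigma) else 1
            ion_int[i, ] <- baseline * spec$effect_matrix[g_idx[i], ] * noise
        }
        if (n_bg > 0) {
            # inactive (forceps-off) segments: a shared instrument-background
            # signature at the 1% level -- a few dominant contamination ions
            # over a low flat residual. Near-zero total signal AND a distinct
            # spectral direction, which cosine k-means burn detection keys on
            bg_profile <- rep(0.5, spec$n_ions)
            spikes <- sample(spec$n_ions, max(3L, round(0.03 * spec$n_ions)))
            bg_profile[spikes] <- 500
            for (i in seq_len(n_bg)) {
                noise <- if (spec$noise_sigma > 0)
                    stats::rlnorm(spec$n_ions, 0, max(spec$noise_sigma, 0.2))
                    else 1
                ion_int[n_spectra + i, ] <- 0.01 * bg_profile * noise
            }
        }

        meta <- data.frame(
            sample_id = c(sprintf("%s_r%d", sample_id[rows$sample], rows$rep),
                          if (n_bg > 0) sprintf("BG_%03d", seq_len(n_bg))),
            patient_id = c(sample_id[rows$sample],
                           if (n_bg > 0) rep(NA_character_, n_bg)),
            group = c(groups[rows$sample],
                      if (n_bg > 0) rep("background", n_bg)),
            sex = c(sex[rows$sample], if (n_bg > 0) rep(NA_character_, n_bg)),
            replicate = c(rows$rep, if (n_bg > 0) rep(1L, n_bg)),
            active = active,
            stringsAsFactors = FALSE)

        if (render == "peaks") {
            out <- SpectrumCohort(ion_mz, ion_int, meta,
                                  massWindow = spec$mz_range)
        } else {
            axis <- buildMzAxis(spec$mz_range, spec$axis_step)
            sd_da <- (spec$peak_fwhm / 2.354820045) * ion_mz / 600
            mat <- matrix(0, nrow(ion_int), length(axis))
            # render each ion's Gaussian only on its +/- 4 sd neighbourhood
            for (j in seq_len(spec$n_ions)) {
                lo <- findInterval(ion_mz[j] - 4 * sd_da[j], axis) + 1L
                hi <- findInterval(ion_mz[j] + 4 * sd_da[j], axis)
                if (hi < lo) next
                shape <- exp(-0.5 * ((axis[lo:hi] - ion_mz[j]) / sd_da[j])^2)
                mat[, lo:hi] <- mat[, lo:hi] + outer(ion_int[, j], shape)
            }
            if (spec$baseline_noise > 0)
                mat <- mat + matrix(stats::runif(length(mat), 0,
                                                 spec$baseline_noise),
                                    nrow(mat))
            out <- SpectrumCohort(axis, mat, meta, massWindow = spec$mz_range)
        }
        attr(out, "ion_mz") <- ion_mz
        attr(out, "effect_matrix") <- spec$effect_matrix
        out
    })
}

#' Specification of a synthetic MSI datacube
#'
#' Describes an imaging acquisition over a tissue section with spatially
#' contiguous compartments (background, normal, stroma, tumour by default),
#' each carrying a distinct multiplicative spectral signature. Background
#' pixels emit only a low-intensity residual (signature scaled by 0.01).
#'
#' The default compartment map is a nested layout on a `width x height` grid:
#' a background border, a normal-tissue field, a stroma ring and a tumour
#' core. Each non-background compartment gets `ions_per_compartment` private
#' ions boosted `effect_size`-fold over a shared baseline so that relative
#' (RMS-normalised) pixel profiles are comparable across compartments.
#'
#' @param width,height image size in pixels.
#' @param compartment_map optional character matrix (height x width, rows =
#'   y) of labels among "background", "normal", "stroma", "tumour"; NULL uses
#'   the nested default layout.
#' @param signature_matrix optional compartments x n_ions non-negative matrix
#'   (rownames = compartment labels); NULL builds the block design.
#' @param n_ions ion count.
#' @param ions_per_compartment,effect_size block-design parameters.
#' @param mz_range ion placement window in Da.
#' @param noise_sigma log-scale noise sd.
#' @param peak_fwhm,axis_step profile rendering parameters (see [cohortSpec()]).
#' @param seed integer seed.
#' @return a list with class "cubeSpec".
#' @export
cubeSpec <- function(width = 40, height = 40,
                     compartment_map = NULL,
                     signature_matrix = NULL,
                     n_ions = 120,
                     ions_per_compartment = 6,
                     effect_size = 5,
                     mz_range = c(700, 760),
                     noise_sigma = 0.3,
                     peak_fwhm = 0.05,
                     axis_step = 0.01,
                     seed = 1L) {
    width <- as.integer(width); height <- as.integer(height)
    if (is.null(compartment_map))
        compartment_map <- defaultCompartmentMap(width, height)
    compartment_map <- as.matrix(compartment_map)
    .assert(nrow(compartment_map) == height && ncol(compartment_map) == width,
            "compartment_map must be height (%d) x width (%d), got %d x %d",
            height, width, nrow(compartment_map), ncol(compartment_map))
    comps <- sort(unique(as.vector(compartment_map)))
    .assert("background" %in% comps && length(comps) >= 2,
            "compartment_map needs at least one background and one tissue pixel")
    if (is.null(signature_matrix)) {
        tissue <- setdiff(comps, "background")
        .assert(length(tissue) * ions_per_compartment <= n_ions,
                "not enough ions for %d private ions per compartment",
                ions_per_compartment)
        signature_matrix <- matrix(1, length(comps), n_ions,
                                   dimnames = list(comps, NULL))
        for (i in seq_along(tissue)) {
            idx <- (i - 1L) * ions_per_compartment +
                seq_len(ions_per_compartment)
            signature_matrix[tissue[i], idx] <- effect_size
        }
        # background: a low contamination signature (flat residual plus a few
        # dominant ions at the high end of the axis, away from the private
        # tissue ions), ~1% of tissue signal and a distinct direction
        bg <- rep(0.002, n_ions)
        bg[n_ions - seq_len(min(3L, n_ions)) + 1L] <- 0.5
        signature_matrix["background", ] <- bg
    }
    signature_matrix <- as.matrix(signature_matrix)
    .assert(!is.null(rownames(signature_matrix)) &&
            setequal(rownames(signature_matrix), comps),
            "signature_matrix rows must be named by the compartment labels (%s)",
            paste(comps, collapse = ", "))
    .assert(ncol(signature_matrix) == n_ions,
            "signature_matrix must have n_ions (%d) columns, got %d",
            n_ions, ncol(signature_matrix))
    .assert(all(signature_matrix >= 0), "signatures must be non-negative")
    structure(list(width = width, height = height,
                   compartment_map = compartment_map,
                   signature_matrix = signature_matrix,
                   n_ions = as.integer(n_ions),
                   mz_range = as.numeric(mz_range),
                   noise_sigma = noise_sigma, peak_fwhm = peak_fwhm,
                   axis_step = axis_step, seed = as.integer(seed)),
              class = "cubeSpec")
}

#' Default nested compartment layout
#'
#' Background border (2 px), normal field, stroma ring, tumour core; the
#' tumour sits in the lower-right quadrant surrounded by stroma, emulating a
#' localized lesion with stromal infiltration inside normal tissue.
#'
#' @param width,height grid size in pixels.
#' @return character matrix (height x width).
#' @export
defaultCompartmentMap <- function(width = 40, height = 40) {
    m <- matrix("normal", height, width)
    m[c(1:2, height - 1:0), ] <- "background"
    m[, c(1:2, width - 1:0)] <- "background"
    cx <- round(width * 0.62); cy <- round(height * 0.62)
    r_stroma <- round(min(width, height) * 0.28)
    r_tumour <- round(min(width, height) * 0.16)
    for (y in 3:(height - 2)) for (x in 3:(width - 2)) {
        d <- sqrt((x - cx)^2 + (y - cy)^2)
        if (d <= r_tumour) m[y, x] <- "tumour"
        else if (d <= r_stroma) m[y, x] <- "stroma"
    }
    m
}

#' Generate a synthetic MSI datacube
#'
#' Per pixel, ion intensities are drawn as
#' `baseline x compartment signature x lognormal(0, noise_sigma)`; background
#' pixels carry a 1% residual signature. Pixels are laid out 0-based,
#' row-major. The planted compartment map is kept in
#' `cube@metadata$compartment_map` (and as a per-pixel vector in
#' `cube@metadata$compartment`).
#'
#' @param spec a [cubeSpec()].
#' @param render "profile" for dense Gaussian-peak pixel spectra, "peaks" for
#'   the ion-level datacube.
#' @return an [MSIDataCube-class].
#' @export
generateCube <- function(spec, render = c("profile", "peaks")) {
    stopifnot(inherits(spec, "cubeSpec"))
    render <- match.arg(render)
    withr::with_seed(spec$seed, {
        ion_mz <- sort(stats::runif(spec$n_ions, spec$mz_range[1] + 1,
                                    spec$mz_range[2] - 1))
        baseline <- exp(stats::runif(spec$n_ions, log(50), log(500)))

        # Equalise expected pixel energy across tissue compartments: ions
        # whose signature differs between tissue compartments (the planted
        # markers) all share one common baseline. With fully random baselines
        # one compartment's markers can dominate total signal, and RMS/TIC
        # normalisation would then induce spurious fold changes on every
        # unmodulated ion; a shared marker baseline keeps compartment
        # energies equal while preserving the planted effect ratios exactly.
        sig <- spec$signature_matrix
        tissue <- setdiff(rownames(sig), "background")
        if (length(tissue) > 1) {
            modulated <- apply(sig[tissue, , drop = FALSE], 2,
                               function(col) length(unique(col)) > 1)
            baseline[modulated] <- stats::median(baseline)
        }

        # row-major pixel order: y advances slowest
        grid <- expand.grid(x = seq_len(spec$width) - 1L,
                            y = seq_len(spec$height) - 1L)
        comp <- spec$compartment_map[cbind(grid$y + 1L, grid$x + 1L)]
        n_px <- nrow(grid)
        ion_int <- matrix(0, n_px, spec$n_ions)
        for (i in seq_len(n_px)) {
            noise <- if (spec$noise_sigma > 0)
                stats::rlnorm(spec$n_ions, 0, spec$noise_sigma) else 1
            ion_int[i, ] <- baseline * sig[comp[i], ] * noise
        }

        meta <- list(compartment_map = spec$compartment_map,
                     compartment = comp, ion_mz = ion_mz,
                     signature_matrix = spec$signature_matrix,
                     baseline = baseline)
        if (render == "peaks") {
            MSIDataCube(ion_mz, ion_int, as.matrix(grid),
                        dim = c(spec$width, spec$height), metadata = meta)
        } else {
            axis <- buildMzAxis(spec$mz_range, spec$axis_step)
            sd_da <- (spec$peak_fwhm / 2.354820045) * ion_mz / 600
            mat <- matrix(0, n_px, length(axis))
            for (j in seq_len(spec$n_ions)) {
                lo <- findInterval(ion_mz[j] - 4 * sd_da[j], axis) + 1L
                hi <- findInterval(ion_mz[j] + 4 * sd_da[j], axis)
                if (hi < lo) next
                shape <- exp(-0.5 * ((axis[lo:hi] - ion_mz[j]) / sd_da[j])^2)
                mat[, lo:hi] <- mat[, lo:hi] + outer(ion_int[, j], shape)
            }
            MSIDataCube(axis, mat, as.matrix(grid),
                        dim = c(spec$width, spec$height), metadata = meta)
        }
    })
}

#' Generate a synthetic clinical cohort with technical replicates
#'
#' Emulates a clinical REIMS feature table: binary patient labels (default 16
#' positive / 8 negative), technical replicate spectra per patient,
#' label-informative features, and batch-confounded features that shift with
#' an acquisition batch uncorrelated with the label. Replicates of one patient
#' share the patient's label, batch and a patient-level random effect.
#'
#' Feature model (standard-normal baseline): informative features add
#' `effect x label`, batch features add `effect x batch`; every feature adds
#' a patient effect (sd `patient_sd`) and replicate noise (sd `noise_sd`).
#'
#' @param n_patients total patients (>= 4).
#' @param n_positive patients in the positive class (default 2/3 of cohort).
#' @param replicates technical replicates per patient.
#' @param n_features feature count.
#' @param n_informative features shifted by the label.
#' @param n_batch features shifted by the batch variable.
#' @param effect mean shift in noise-sd units.
#' @param noise_sd replicate-level noise sd.
#' @param patient_sd patient-level random-effect sd.
#' @param seed integer seed.
#'
#' @return a list: `features` (rows = spectra), `meta` (spectrum, patient,
#'   label, batch, replicate), `feature_roles` ("informative", "batch",
#'   "null" per feature).
#' @export
generateClinicalCohort <- function(n_patients = 24,
                                   n_positive = round(2 * n_patients / 3),
                                   replicates = 3,
                                   n_features = 200,
                                   n_informative = 20,
                                   n_batch = 20,
                                   effect = 2,
                                   noise_sd = 1,
                                   patient_sd = 0.5,
                                   seed = 1L) {
    .assert(n_patients >= 4, "insufficient cohort: need at least 4 patients")
    .assert(n_informative + n_batch <= n_features,
            "n_informative + n_batch must not exceed n_features")
    .assert(n_positive >= 2 && n_patients - n_positive >= 2,
            "need at least 2 patients per class")
    withr::with_seed(as.integer(seed), {
        label <- c(rep(1L, n_positive), rep(0L, n_patients - n_positive))
        batch <- sample(rep_len(0:1, n_patients))  # independent of label
        roles <- rep("null", n_features)
        roles[seq_len(n_informative)] <- "informative"
        if (n_batch > 0)
            roles[n_informative + seq_len(n_batch)] <- "batch"

        shift <- matrix(0, n_patients, n_features)
        shift[, roles == "informative"] <- effect * label
        shift[, roles == "batch"] <- effect * batch
        patient_eff <- matrix(stats::rnorm(n_patients * n_features, 0,
                                           patient_sd),
                              n_patients)

        idx <- rep(seq_len(n_patients), each = replicates)
        feat <- (shift + patient_eff)[idx, , drop = FALSE] +
            matrix(stats::rnorm(length(idx) * n_features, 0, noise_sd),
                   length(idx))
        colnames(feat) <- sprintf("F%04d", seq_len(n_features))
        meta <- data.frame(
            sample_id = sprintf("P%02d_r%d", idx,
                                rep(seq_len(replicates), n_patients)),
            patient_id = sprintf("P%02d", idx),
            label = label[idx], batch = batch[idx],
            replicate = rep(seq_len(replicates), n_patients),
            stringsAsFactors = FALSE)
        list(features = feat, meta = meta, feature_roles = roles)
    })
}

#' Generate a toy compound database
#'
#' Builds a small metabolite reference table in the shape the annotation step
#' consumes: unique compound names (a configurable fraction in lipid
#' shorthand, e.g. `PC(34:2(9Z,12Z))`), monoisotopic neutral masses in
#' [50, 1500] Da, and 1-5 pathway memberships per compound, with pathways
#' grouped into subclasses.
#'
#' @param n_compounds number of compounds.
#' @param n_pathways number of distinct pathways.
#' @param lipid_fraction fraction of compounds given lipid-style names.
#' @param seed integer seed.
#' @return data.frame with columns `compound_name`, `monoisotopic_mass`,
#'   `formula`, `pathway`, `subclass` (one row per compound-pathway pair).
#' @export
generateCompoundDB <- function(n_compounds = 100, n_pathways = 12,
                               lipid_fraction = 0.6, seed = 1L) {
    .assert(n_compounds >= 1 && n_pathways >= 1, "counts must be positive")
    withr::with_seed(as.integer(seed), {
        classes <- c("PC", "PE", "PS", "PI", "PG", "TG", "LPE", "LPC")
        n_lip <- round(lipid_fraction * n_compounds)
        lipid_names <- character(0)
        while (length(lipid_names) < n_lip) {
            cand <- sprintf("%s(%d:%d/%d:%d)",
                            sample(classes, n_lip, TRUE),
                            sample(12:24, n_lip, TRUE),
                            sample(0:6, n_lip, TRUE),
                            sample(12:24, n_lip, TRUE),
                            sample(0:6, n_lip, TRUE))
            lipid_names <- unique(c(lipid_names, cand))
        }
        lipid_names <- lipid_names[seq_len(n_lip)]
        other_names <- sprintf("metabolite_%03d", seq_len(n_compounds - n_lip))
        names_all <- c(lipid_names, other_names)
        mass <- stats::runif(n_compounds, 50, 1500)

        subclasses <- sprintf("subclass_%02d",
                              rep_len(seq_len(max(1, n_pathways %/% 3)),
                                      n_pathways))
        pathways <- sprintf("pathway_%02d", seq_len(n_pathways))
        rows <- lapply(seq_len(n_compounds), function(i) {
            k <- sample(1:5, 1)
            pw <- sample(n_pathways, min(k, n_pathways))
            data.frame(compound_name = names_all[i],
                       monoisotopic_mass = mass[i],
                       formula = NA_character_,
                       pathway = pathways[pw], subclass = subclasses[pw],
                       stringsAsFactors = FALSE)
        })
        db <- do.call(rbind, rows)
        rownames(db) <- NULL
        validateCompoundDB(db)
        db
    })
}

#' Validate a compound database table
#'
#' Checks the invariants of the reference-table schema: positive masses,
#' unique compound names (across their per-compound rows the mass must be
#' constant), non-empty pathway subclasses.
#'
#' @param db data.frame as produced by [generateCompoundDB()] or read from
#'   TSV with the same columns.
#' @return the validated data.frame, invisibly.
#' @export
validateCompoundDB <- function(db) {
    need <- c("compound_name", "monoisotopic_mass", "pathway", "subclass")
    .assert(all(need %in% colnames(db)),
            "compound DB must have columns: %s", paste(need, collapse = ", "))
    .assert(all(db$monoisotopic_mass > 0), "monoisotopic masses must be > 0")
    .assert(all(nzchar(db$subclass)), "every pathway needs a non-empty subclass")
    per <- tapply(db$monoisotopic_mass, db$compound_name,
                  function(m) length(unique(m)))
    .assert(all(per == 1),
            "compound names must be unique (one mass per name)")
    invisible(db)
}
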