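# Generators: determinism, planted truth, null faithfulness, validation.

test_that("cohort generation is a pure function of spec + seed", {
    sp <- cohortSpec(n_groups = 3, samples_per_group = 2,
                     spectra_per_sample = 2, n_ions = 30,
                     mz_range = c(600, 650), seed = 7)
    a <- generateCohort(sp)
    b <- generateCohort(sp)
    expect_identical(intensities(a), intensities(b))
    expect_identical(sampleData(a), sampleData(b))
    c <- generateCohort(cohortSpec(n_groups = 3, samples_per_group = 2,
                                   spectra_per_sample = 2, n_ions = 30,
                                   mz_range = c(600, 650), seed = 8))
    expect_false(identical(intensities(a), intensities(c)))
})

test_that("with unit effects and zero noise all active spectra are identical", {
    sp <- cohortSpec(n_groups = 3, samples_per_group = 2,
                     spectra_per_sample = 2, n_ions = 25,
                     mz_range = c(600, 640),
                     effect_matrix = matrix(1, 3, 25), noise_sigma = 0,
                     background_fraction = 0, seed = 3)
    co <- generateCohort(sp)
    m <- intensities(co)
    for (i in 2:nrow(m)) expect_equal(m[i, ], m[1, ])
})

test_that("inactive acquisition segments are near-zero and flagged", {
    co <- generateCohort(cohortSpec(n_groups = 2, samples_per_group = 4,
                                    spectra_per_sample = 2, n_ions = 40,
                                    mz_range = c(600, 700),
                                    background_fraction = 0.25, seed = 5))
    act <- sampleData(co)$active
    expect_true(any(act) && any(!act))
    tic <- rowSums(intensities(co))
    expect_lt(max(tic[!act]), min(tic[act]) / 5)
})

test_that("invalid cohort specs are rejected", {
    expect_error(cohortSpec(n_groups = 3, n_ions = 10,
                            effect_matrix = matrix(1, 2, 10)),
                 "effect_matrix")
    expect_error(cohortSpec(mz_range = c(700, 600)), "mz_range")
    expect_error(cohortSpec(background_fraction = 1), "background_fraction")
})

test_that("cube generation is deterministic and carries planted truth", {
    sp <- cubeSpec(width = 10, height = 8, n_ions = 30,
                   ions_per_compartment = 3, mz_range = c(700, 720), seed = 4)
    a <- generateCube(sp, render = "peaks")
    b <- generateCube(sp, render = "peaks")
    expect_identical(intensities(a), intensities(b))
    expect_identical(dim(a), c(10L, 8L))
    expect_equal(nrow(coords(a)), 80)
    expect_setequal(unique(a@metadata$compartment),
                    c("background", "normal", "stroma", "tumour"))
})

test_that("noiseless cube with orthogonal signatures is exactly recoverable", {
    map <- matrix(rep(c("background", "tumour"), each = 18), 6, 6)
    sig <- rbind(background = c(1, 1, 0, 0), tumour = c(0, 0, 1, 1))
    sp <- cubeSpec(width = 6, height = 6, compartment_map = map,
                   signature_matrix = sig, n_ions = 4, noise_sigma = 0,
                   mz_range = c(700, 710), seed = 2)
    cube <- generateCube(sp, render = "peaks")
    km <- kmeansCluster(intensities(cube), 2, metric = "cosine", seed = 1)
    expect_equal(ari(km$labels, cube@metadata$compartment), 1)
})

test_that("cube spec validation catches bad dimensions", {
    expect_error(cubeSpec(width = 5, height = 5,
                          compartment_map = matrix("normal", 4, 5)),
                 "compartment_map")
    map <- defaultCompartmentMap(10, 10)
    expect_error(cubeSpec(width = 10, height = 10, compartment_map = map,
                          n_ions = 6,
                          signature_matrix = matrix(1, 2, 6)),
                 "named")
})

test_that("clinical cohort honours the replicate and confounder design", {
    cc <- generateClinicalCohort(seed = 11)
    expect_equal(nrow(cc$features), 24 * 3)
    expect_equal(sum(tapply(cc$meta$label, cc$meta$patient_id, `[`, 1) == 1), 16)
    # replicates share patient label and batch
    expect_true(all(tapply(cc$meta$label, cc$meta$patient_id,
                           function(x) length(unique(x))) == 1))
    expect_true(all(tapply(cc$meta$batch, cc$meta$patient_id,
                           function(x) length(unique(x))) == 1))
    expect_equal(sum(cc$feature_roles == "informative"), 20)
    expect_equal(sum(cc$feature_roles == "batch"), 20)
    expect_identical(cc$features,
                     generateClinicalCohort(seed = 11)$features)
    expect_error(generateClinicalCohort(n_patients = 3),
                 "insufficient cohort")
    expect_error(generateClinicalCohort(n_features = 30, n_informative = 20,
                                        n_batch = 20), "exceed")
})

test_that("zero-effect clinical cohort has no class signal in expectation", {
    cc <- generateClinicalCohort(effect = 0, n_patients = 40, replicates = 2,
                                 n_features = 300, seed = 13)
    pat_mean <- apply(cc$features, 2, tapply,
                      INDEX = cc$meta$patient_id, mean)
    lab <- tapply(cc$meta$label, cc$meta$patient_id, `[`, 1)[rownames(pat_mean)]
    p <- apply(pat_mean, 2, function(f)
        stats::t.test(f[lab == 1], f[lab == 0])$p.value)
    # nominal type-I behaviour: rejection rate near 0.05
    expect_lt(abs(mean(p < 0.05) - 0.05),
              qnorm(0.995) * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("toy compound database obeys its schema invariants", {
    db <- generateCompoundDB(n_compounds = 40, n_pathways = 8, seed = 6)
    expect_identical(db, generateCompoundDB(n_compounds = 40, n_pathways = 8,
                                            seed = 6))
    expect_true(all(db$monoisotopic_mass > 0))
    expect_true(all(nzchar(db$subclass)))
    expect_silent(validateCompoundDB(db))
    one <- generateCompoundDB(n_compounds = 1, n_pathways = 2, seed = 1)
    expect_gte(nrow(one), 1)
    expect_equal(length(unique(one$compound_name)), 1)
})

test_that("a planted compound is found by deprotonated-ion ppm matching", {
    db <- data.frame(compound_name = c("target", "far_a", "far_b"),
                     monoisotopic_mass = c(465.2953, 300.1, 800.5),
                     formula = NA, pathway = "p1", subclass = "s1")
    q <- (465.2953 - 1.007276467) * (1 + 2e-6)  # +2 ppm off the [M-H]- ion
    hits <- matchIons(q, db, defaultAdducts("negative"), ppm_tol = 5)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$compound_name, "target")
    expect_equal(hits$ppm_error, 2, tolerance = 1e-6)
})
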