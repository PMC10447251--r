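# Mean spectrum, gradient peak picking, top-N selection, datacube reduction.

test_that("mean spectrum equals independent column means", {
    co <- generateCohort(cohortSpec(n_groups = 2, samples_per_group = 3,
                                    spectra_per_sample = 1, n_ions = 20,
                                    mz_range = c(600, 640), seed = 4))
    ms <- meanSpectrum(co)
    brute <- apply(intensities(co), 2, mean)
    expect_equal(ms@intensity, unname(brute))

    one <- SpectrumCohort(1:3, rbind(c(1, 5, 2)),
                          data.frame(sample_id = "s"), c(1, 3))
    expect_equal(meanSpectrum(one)@intensity, c(1, 5, 2))
    two <- SpectrumCohort(1:2, rbind(c(0, 2), c(2, 0)),
                          data.frame(sample_id = c("a", "b")), c(1, 2))
    expect_equal(meanSpectrum(two)@intensity, c(1, 1))
})

test_that("gradient peak picking finds interior rise-fall maxima", {
    mono <- MassSpectrum(1:10, 1:10)
    expect_length(gradientPeakPick(mono), 0)

    s <- MassSpectrum(1:5, c(0, 1, 0, 2, 0))
    pk <- gradientPeakPick(s)
    expect_equal(mz(pk), c(2, 4))
    expect_equal(intensities(pk), c(1, 2))

    expect_error(gradientPeakPick(MassSpectrum(1:2, c(0, 1))), "short")
})

test_that("plateau maxima report the centre bin, rounding down", {
    odd <- MassSpectrum(1:7, c(0, 1, 5, 5, 5, 1, 0))
    expect_equal(mz(gradientPeakPick(odd)), 4)
    even <- MassSpectrum(1:6, c(0, 5, 5, 5, 5, 0))
    expect_equal(mz(gradientPeakPick(even)), 3)  # centre of 2..5 rounds down
})

test_that("peak picking matches the exhaustive local-maximum oracle", {
    withr::with_seed(42, {
        for (i in 1:50) {
            y <- runif(200)  # continuous draws: ties have probability zero
            s <- MassSpectrum(seq_len(200), y)
            pk <- gradientPeakPick(s)
            expect_equal(mz(pk), localmax_oracle(y))
        }
    })
})

test_that("noiseless planted Gaussian peaks are recovered within one bin", {
    axis <- buildMzAxis(c(600, 640), 0.001)
    centers <- seq(601, 639, length.out = 20) + runif(20, -0.2, 0.2)
    sd_da <- 0.05 / 2.3548
    y <- rowSums(vapply(centers,
                        function(c0) exp(-0.5 * ((axis - c0) / sd_da)^2),
                        numeric(length(axis))))
    pk <- gradientPeakPick(MassSpectrum(axis, y), min_intensity = 1e-6)
    expect_length(pk, 20)
    expect_true(all(abs(mz(pk) - centers) <= 0.001 + 1e-9))
})

test_that("top-N selection matches brute-force sort-and-slice", {
    pk <- PeakList(c(1, 2, 3), c(5, 9, 1))
    top2 <- topNPeaks(pk, 2)
    expect_equal(sort(intensities(top2), decreasing = TRUE), c(9, 5))
    expect_identical(topNPeaks(pk, 10), pk)
    expect_identical(topNPeaks(topNPeaks(pk, 2), 2), topNPeaks(pk, 2))

    # intensity ties break toward lower m/z
    tie <- PeakList(c(10, 20, 30), c(7, 7, 9))
    expect_equal(mz(topNPeaks(tie, 2)), c(10, 30))

    withr::with_seed(31, {
        for (i in 1:30) {
            n <- sample(5:40, 1)
            p <- PeakList(sort(runif(n, 100, 200)), runif(n))
            k <- sample(seq_len(n), 1)
            got <- topNPeaks(p, k)
            ord <- order(-intensities(p), mz(p))[seq_len(k)]
            expect_equal(mz(got), sort(mz(p)[ord]))
        }
    })
})

test_that("datacube features are peak-window sums with nearest-peak ties", {
    ax <- seq(100, 100.9, by = 0.1)
    m <- rbind(c(0, 1, 2, 3, 0, 0, 0, 4, 0, 0))
    cube <- MSIDataCube(ax, m, cbind(x = 0L, y = 0L), c(1, 1))
    # tol under one bin spacing: feature = the peak bin only
    f1 <- buildDataCube(cube, PeakList(c(100.3, 100.7), c(3, 4)), tol = 0.04)
    expect_equal(intensities(f1)[1, ], c(3, 4))
    # tol spanning the 3 bins with intensities (1, 2, 3) sums to 6
    f2 <- buildDataCube(cube, PeakList(c(100.2, 100.7), c(2, 4)), tol = 0.11)
    expect_equal(intensities(f2)[1, 1], 6)

    expect_true(all(intensities(f2) >= 0))
})

test_that("compartment signatures survive peak-space reduction", {
    sp <- cubeSpec(width = 10, height = 10, n_ions = 25,
                   ions_per_compartment = 4, noise_sigma = 0,
                   mz_range = c(700, 725), seed = 6)
    cube <- generateCube(sp)  # dense profile render
    pk <- topNPeaks(gradientPeakPick(meanSpectrum(cube), min_intensity = 1e-9),
                    25)
    red <- buildDataCube(cube, pk)
    comp <- cube@metadata$compartment
    sig <- sp$signature_matrix
    ion_mz <- cube@metadata$ion_mz
    # map features back to planted ions, compare compartment mean profiles
    feat2ion <- vapply(mz(red), function(m) which.min(abs(ion_mz - m)),
                       integer(1))
    baseline <- cube@metadata$baseline
    for (cm in setdiff(rownames(sig), "background")) {
        mu <- colMeans(intensities(red)[comp == cm, , drop = FALSE])
        planted <- (baseline * sig[cm, ])[feat2ion]
        cosine <- sum(mu * planted) / sqrt(sum(mu^2) * sum(planted^2))
        expect_gte(cosine, 0.99)
    }
})
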