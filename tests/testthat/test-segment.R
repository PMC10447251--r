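# Burn detection, t-SNE, k-means, elbow selection, cube segmentation, purity.

test_that("burn detection recovers planted active/inactive spectra exactly", {
    co <- generateCohort(cohortSpec(n_groups = 2, samples_per_group = 5,
                                    spectra_per_sample = 1, n_ions = 60,
                                    mz_range = c(600, 700),
                                    background_fraction = 0.5, seed = 17),
                         render = "peaks")
    mask <- detectActiveSpectra(co, seed = 1)
    expect_identical(mask, sampleData(co)$active)
    expect_identical(mask, detectActiveSpectra(co, seed = 1))
})

test_that("with two all-active intensity tiers the brighter tier is marked active", {
    withr::with_seed(3, {
        hi <- matrix(rlnorm(10 * 30, log(100), 0.1), 10)
        lo <- matrix(rlnorm(10 * 30, log(100), 0.1), 10)
        lo[, 1:10] <- lo[, 1:10] * 20  # different direction, dimmer overall
        hi[, 11:30] <- hi[, 11:30] * 40
    })
    co <- SpectrumCohort(1:30, rbind(hi, lo),
                         data.frame(sample_id = sprintf("s%02d", 1:20)),
                         c(1, 30))
    mask <- detectActiveSpectra(co, seed = 2)
    tiers <- rep(c("hi", "lo"), each = 10)
    expect_true(all(mask[tiers == "hi"]) && !any(mask[tiers == "lo"]))
})

test_that("degenerate identical-spectra cohorts are refused", {
    co <- SpectrumCohort(1:4, matrix(1, 5, 4),
                         data.frame(sample_id = as.character(1:5)), c(1, 4))
    expect_error(detectActiveSpectra(co), "degenerate")
})

test_that("t-SNE contract: shape, determinism, class separation", {
    eff <- matrix(1, 2, 60)
    eff[1, 1:8] <- 5; eff[2, 9:16] <- 5
    co <- generateCohort(cohortSpec(n_groups = 2, samples_per_group = 20,
                                    spectra_per_sample = 1, n_ions = 60,
                                    effect_matrix = eff, noise_sigma = 0.1,
                                    background_fraction = 0, seed = 8,
                                    group_names = c("g1", "g2")),
                         render = "peaks")
    x <- intensities(co)
    emb <- tsneEmbed(x, preset = "cohort", perplexity = 10, seed = 5)
    expect_equal(dim(emb), c(40, 3))
    expect_identical(emb, tsneEmbed(x, preset = "cohort", perplexity = 10,
                                    seed = 5))
    d <- as.matrix(dist(emb))
    grp <- sampleData(co)$group
    within <- mean(d[grp == "g1", grp == "g1"])
    between <- mean(d[grp == "g1", grp == "g2"])
    expect_gt(between, within)
    expect_error(tsneEmbed(x, perplexity = 30), "perplexity")
})

test_that("k-means separates planted blobs and honours k = n", {
    withr::with_seed(12, {
        x <- rbind(matrix(rnorm(10 * 2, 0, 0.1), 10),
                   matrix(rnorm(10 * 2, 5, 0.1), 10))
    })
    km <- kmeansCluster(x, 2, "euclidean", seed = 3)
    expect_equal(ari(km$labels, rep(1:2, each = 10)), 1)

    km_n <- kmeansCluster(x, nrow(x), "euclidean", seed = 3)
    expect_equal(km_n$wcss, 0)
    expect_equal(sort(unique(km_n$labels)), 1:nrow(x))
    expect_error(kmeansCluster(x, nrow(x) + 1, "euclidean"), "k must be")
})

test_that("small-instance k-means equals the exhaustive-partition optimum", {
    withr::with_seed(99, {
        for (i in 1:100) {
            n <- sample(4:8, 1)
            x <- matrix(rnorm(n * 2), n)
            km <- kmeansCluster(x, 2, "euclidean", n_replicates = 40, seed = i)
            expect_equal(km$wcss, exhaustive_kmeans2(x), tolerance = 1e-8)
        }
    })
})

test_that("cluster labels are permutation-equivariant under row reordering", {
    withr::with_seed(21, {
        x <- rbind(matrix(rnorm(8 * 3, 0), 8), matrix(rnorm(8 * 3, 6), 8))
        perm <- sample(nrow(x))
    })
    a <- kmeansCluster(x, 2, "euclidean", seed = 4)$labels
    b <- kmeansCluster(x[perm, ], 2, "euclidean", seed = 4)$labels
    expect_equal(ari(a[perm], b), 1)
})

test_that("elbow rule maximises WCSS curvature with smaller-k ties", {
    expect_equal(selectElbow(c(100, 40, 35, 33), 1:4), 2)
    expect_equal(selectElbow(c(100, 80, 60, 40, 20), 1:5), 2)  # linear: tie
    expect_error(selectElbow(c(10, 5), 1:2), "at least 3")
})

test_that("elbow selection recovers the planted blob count", {
    centers <- rbind(c(0, 0), c(10, 0), c(5, 8.66))  # near-equilateral
    hits <- 0
    for (s in 1:10) {
        withr::with_seed(s, {
            x <- do.call(rbind, lapply(1:3, function(i)
                cbind(rnorm(12, centers[i, 1], 0.4),
                      rnorm(12, centers[i, 2], 0.4))))
        })
        sel <- elbowSelectK(x, 1:6, "euclidean", seed = s)
        expect_true(all(diff(sel$wcss_curve) <= 1e-8))
        hits <- hits + (sel$k == 3)
    }
    expect_gte(hits, 9)
})

test_that("noiseless cube segmentation reproduces the compartment map", {
    sp <- cubeSpec(width = 14, height = 14, n_ions = 40,
                   ions_per_compartment = 5, noise_sigma = 0,
                   mz_range = c(700, 740), seed = 2)
    cube <- generateCube(sp, render = "peaks")
    seg <- segmentCube(cube, k = 4, seed = 11)
    expect_equal(ari(seg$segmentation@labels, cube@metadata$compartment), 1)
    expect_identical(seg$background,
                     cube@metadata$compartment == "background")
})

test_that("manual background masks take precedence and gate the second pass", {
    sp <- cubeSpec(width = 10, height = 10, n_ions = 30,
                   ions_per_compartment = 4, mz_range = c(700, 730), seed = 5)
    cube <- generateCube(sp, render = "peaks")
    manual <- cube@metadata$compartment %in% c("background", "normal")
    seg <- segmentCube(cube, k = 4, background_mask = manual,
                       second_pass_k = 2, seed = 6)
    expect_identical(seg$background, manual)
    expect_true(all(is.na(seg$tissue_labels[manual])))
    expect_true(all(!is.na(seg$tissue_labels[!manual])))
    expect_error(segmentCube(cube, k = 4, background_mask = c(TRUE, FALSE)),
                 "mask length")
})

test_that("purity percentages are per-group and sum to 100", {
    one <- purityTable(rep(1, 12), rep(c("x", "y"), 6))
    expect_true(all(one$pct_of_group == 100))

    # 39 male spectra, 30 of them in cluster 1
    labels <- c(rep(1, 30), rep(2, 9), rep(1, 5), rep(2, 45))
    sex <- c(rep("M", 39), rep("F", 50))
    tab <- purityTable(labels, sex)
    m1 <- tab$pct_of_group[tab$cluster == "1" & tab$group == "M"]
    expect_equal(m1, 100 * 30 / 39, tolerance = 1e-12)
    sums <- tapply(tab$pct_of_group, tab$group, sum)
    expect_equal(as.vector(sums), rep(100, 2), tolerance = 1e-9)
})
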