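# LOPO folds, SVM, feature refinement, patient-level evaluation.

test_that("LOPO folds partition patients with replicates held out together", {
    cc <- generateClinicalCohort(seed = 2)
    folds <- lopoFolds(cc$meta$patient_id, cc$meta$label)
    expect_length(folds, 24)
    tests <- unlist(lapply(folds, `[[`, "test"))
    expect_setequal(tests, seq_len(nrow(cc$meta)))           # union = cohort
    expect_equal(anyDuplicated(tests), 0)                    # disjoint
    for (f in folds) {
        expect_length(f$test, 3)  # all replicates of the patient together
        expect_equal(length(unique(cc$meta$patient_id[f$test])), 1)
        expect_length(intersect(f$train, f$test), 0)
    }
    expect_error(lopoFolds(c("p1", NA)), "patient_id")
    expect_error(lopoFolds(c("p1", "p2", "p3"), c("x", "x", "y")),
                 "2 patients per class")
})

test_that("a linearly separable toy set is classified without error", {
    withr::with_seed(14, {
        x <- rbind(matrix(rnorm(20, 0, 0.2), 10), matrix(rnorm(20, 5, 0.2), 10))
    })
    y <- rep(c("neg", "pos"), each = 10)
    pred <- fitPredictSVM(x, y, x)
    expect_equal(pred, y)
})

test_that("the 1-D margin midpoint matches a brute-force margin search", {
    # classes {-2,-1} and {1,2}: the maximum-margin threshold is 0
    x <- matrix(c(-2, -1, 1, 2), 4)
    y <- c("a", "a", "b", "b")
    test_x <- matrix(c(-0.4, 0.4, -3, 3), 4)
    pred <- fitPredictSVM(x, y, test_x)
    # brute-force: best threshold = midpoint of the closest opposite pair
    thr <- (max(x[y == "a", 1]) + min(x[y == "b", 1])) / 2
    want <- ifelse(test_x[, 1] < thr, "a", "b")
    expect_equal(pred, want)
})

test_that("patient metrics obey their defining identities exactly", {
    # TP=3, FN=1, TN=4, FP=0 at one spectrum per patient
    truth <- rep(c("mut", "wt"), c(4, 4))
    pred <- c("mut", "mut", "mut", "wt", rep("wt", 4))
    rep1 <- evaluateClassifier(pred, sprintf("p%d", 1:8), truth, "mut")
    expect_equal(unname(rep1@confusion), c(3, 1, 4, 0))
    expect_equal(unname(rep1@metrics),
                 c(0.75, 1.0, 0.0, 0.875))

    perfect <- evaluateClassifier(truth, sprintf("p%d", 1:8), truth, "mut")
    expect_equal(unname(perfect@metrics), c(1, 1, 0, 1))

    withr::with_seed(33, {
        for (i in 1:25) {
            n <- sample(6:20, 1)
            tr <- sample(c("mut", "wt"), n, replace = TRUE)
            tr[1:2] <- "mut"; tr[3:4] <- "wt"
            pd <- sample(c("mut", "wt"), n, replace = TRUE)
            r <- evaluateClassifier(pd, sprintf("p%d", 1:n), tr, "mut")
            m <- r@metrics
            expect_identical(m[["fpr"]], 1 - m[["tnr"]])
            expect_identical(m[["balanced_accuracy"]],
                             (m[["tpr"]] + m[["tnr"]]) / 2)
            expect_equal(unname(r@confusion["TP"] + r@confusion["FN"]),
                         sum(tr == "mut"))
        }
    })
})

test_that("replicate ties aggregate to the positive class", {
    pred <- c("mut", "wt")  # 1-1 tie for one patient
    r <- evaluateClassifier(pred, c("p1", "p1"), c("wt", "wt"), "mut")
    expect_equal(r@patientPredictions$predicted, "mut")
})

test_that("feature refinement recovers planted informative features", {
    cc <- generateClinicalCohort(seed = 21)
    sel <- refineFeatures(cc$features, cc$meta$label, batch = cc$meta$batch,
                          target_k = 50, seed = 1)
    roles <- cc$feature_roles[sel]
    expect_gte(sum(roles == "informative"), 18)
    expect_lte(sum(roles == "batch"), 2)
})

test_that("refinement is monotone in target_k and the identity at k = p", {
    cc <- generateClinicalCohort(n_patients = 12, n_positive = 6,
                                 n_features = 60, n_informative = 8,
                                 n_batch = 0, seed = 8)
    all_sel <- refineFeatures(cc$features, cc$meta$label, target_k = 60,
                              seed = 2)
    expect_equal(unname(all_sel), 1:60)
    s40 <- refineFeatures(cc$features, cc$meta$label, target_k = 40, seed = 2)
    s20 <- refineFeatures(cc$features, cc$meta$label, target_k = 20, seed = 2)
    s10 <- refineFeatures(cc$features, cc$meta$label, target_k = 10, seed = 2)
    expect_true(all(s20 %in% s40))
    expect_true(all(s10 %in% s20))
    expect_warning(refineFeatures(cc$features, cc$meta$label, target_k = 100,
                                  seed = 2), "all")
})

test_that("batch-only cohorts contribute no batch features to the selection", {
    cc <- generateClinicalCohort(n_informative = 0, n_batch = 20, seed = 31)
    sel <- refineFeatures(cc$features, cc$meta$label, batch = cc$meta$batch,
                          target_k = 50, seed = 3)
    expect_equal(sum(cc$feature_roles[sel] == "batch"), 0)
})

test_that("leakage-free LOPO separates the standard synthetic cohort", {
    cc <- generateClinicalCohort(seed = 5)
    rep <- lopoEvaluate(cc$features, cc$meta, target_k = 50,
                        use_batch = TRUE, seed = 7)
    expect_gte(classifierMetrics(rep)[["balanced_accuracy"]], 0.9)
    expect_equal(sum(rep@confusion[c("TP", "FN")]), 16)
    expect_equal(sum(rep@confusion[c("TN", "FP")]), 8)
})

test_that("refined-feature t-SNE keeps the clinical preset contract", {
    cc <- generateClinicalCohort(seed = 9)
    sel <- refineFeatures(cc$features, cc$meta$label, target_k = 50, seed = 1)
    emb <- visualizeRefined(cc$features[, sel], seed = 4)
    expect_equal(dim(emb), c(nrow(cc$features), 3))
    expect_identical(emb, visualizeRefined(cc$features[, sel], seed = 4))
    g <- cc$meta$label
    d <- as.matrix(dist(emb))
    expect_gt(mean(d[g == 1, g == 0]), mean(d[g == 1, g == 1]))
})
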