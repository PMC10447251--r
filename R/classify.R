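# Replicate-aware binary SVM classification with recursive feature
# refinement and leave-one-patient-out cross-validation.

#' Leave-one-patient-out folds
#'
#' One fold per patient; all of a patient's technical-replicate spectra form
#' the test set of that fold, so no patient contributes to both sides of a
#' split.
#'
#' @param patient_id patient identifier per spectrum (no missing values).
#' @param label optional class label per spectrum; when supplied, at least 2
#'   patients per class are required.
#' @return list of folds, each `list(train = indices, test = indices)`,
#'   ordered by patient id.
#' @export
lopoFolds <- function(patient_id, label = NULL) {
    .assert(!anyNA(patient_id) && all(nzchar(as.character(patient_id))),
            "every spectrum needs a patient_id")
    patient_id <- as.character(patient_id)
    if (!is.null(label)) {
        per_patient <- tapply(as.character(label), patient_id,
                              function(l) unique(l)[1])
        .assert(all(table(per_patient) >= 2),
                "need at least 2 patients per class")
    }
    patients <- sort(unique(patient_id))
    lapply(patients, function(p) {
        test <- which(patient_id == p)
        list(patient = p, train = setdiff(seq_along(patient_id), test),
             test = test)
    })
}

# Mean absolute linear-SVM weight per feature across inner CV folds.
.svmFeatureWeights <- function(x, y, folds_idx, C) {
    w_acc <- numeric(ncol(x))
    n_used <- 0L
    for (f in unique(folds_idx)) {
        tr <- which(folds_idx != f)
        if (length(unique(y[tr])) < 2) next
        fit <- .fitLinearSVM(x[tr, , drop = FALSE], y[tr], C)
        w_acc <- w_acc + abs(.svmWeights(fit))
        n_used <- n_used + 1L
    }
    if (n_used == 0L) {
        fit <- .fitLinearSVM(x, y, C)
        return(abs(.svmWeights(fit)))
    }
    w_acc / n_used
}

.fitLinearSVM <- function(x, y, C = 1) {
    y <- factor(y)
    .assert(nlevels(y) == 2,
            "degenerate fold: training data must contain both classes")
    wts <- length(y) / (2 * table(y))  # inverse class frequency
    e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE,
               class.weights = wts)
}

.svmWeights <- function(fit) {
    as.numeric(t(fit$coefs) %*% fit$SV)
}

#' Fit a linear SVM and predict test labels
#'
#' Linear-kernel maximum-margin classifier with penalty `C` and balanced
#' (inverse-class-frequency) class weights, robust to the 2:1 class imbalance
#' of the clinical design. Prediction uses the signed decision value; a test
#' point exactly on the boundary (decision value 0) is assigned to the class
#' with the lower label id (first factor level) as the documented tie-break.
#'
#' @param train_x,train_y training matrix and labels (2 classes).
#' @param test_x matrix of test items.
#' @param C regularisation parameter (default 1).
#' @return character/level vector of predicted labels for `test_x`.
#' @export
fitPredictSVM <- function(train_x, train_y, test_x, C = 1) {
    fit <- .fitLinearSVM(as.matrix(train_x), train_y, C)
    dec <- attr(stats::predict(fit, as.matrix(test_x),
                               decision.values = TRUE), "decision.values")
    # decision column "A/B": positive values vote for A
    parts <- strsplit(colnames(dec)[1], "/")[[1]]
    lv <- levels(factor(train_y))
    unname(ifelse(dec[, 1] > 0, parts[1],
                  ifelse(dec[, 1] < 0, parts[2], lv[1])))
}

# deterministic inner CV fold assignment, stratified by label
.innerFolds <- function(y, k) {
    idx <- seq_along(y)
    f <- integer(length(y))
    for (cl in unique(y)) {
        i <- sample(idx[y == cl])
        f[i] <- rep_len(seq_len(k), length(i))
    }
    f
}

#' Recursive feature refinement
#'
#' Backward elimination on a linear SVM: at each step the fraction
#' `drop_frac` of surviving features with the smallest mean absolute weight
#' across `inner_folds` cross-validation fits is removed, until `target_k`
#' features remain (partial final steps drop only enough to land exactly on
#' `target_k`). When a batch covariate is supplied, features more associated
#' with the batch than with the label (one-way ANOVA F ratio) are removed
#' first — the "spurious background factor" filter. Deterministic given the
#' seed; the elimination path does not depend on `target_k`, so the selected
#' set at a smaller `target_k` is always a subset of the set at a larger one.
#'
#' @param x feature matrix (items x features, named columns recommended).
#' @param y binary labels.
#' @param batch optional batch covariate per item.
#' @param target_k number of features to retain (default 50).
#' @param C SVM penalty.
#' @param drop_frac fraction of surviving features dropped per step.
#' @param inner_folds inner CV folds for weight averaging.
#' @param seed integer seed (inner fold assignment).
#' @return integer vector of selected column indices (named when `x` has
#'   column names), in ascending index order.
#' @export
refineFeatures <- function(x, y, batch = NULL, target_k = 50, C = 1,
                           drop_frac = 0.25, inner_folds = 3, seed = 1L) {
    x <- as.matrix(x)
    p <- ncol(x)
    if (target_k >= p) {
        if (target_k > p)
            warning("target_k exceeds the number of features; returning all")
        sel <- seq_len(p)
        names(sel) <- colnames(x)
        return(sel)
    }
    surviving <- seq_len(p)
    if (!is.null(batch) && length(unique(batch)) > 1) {
        f_label <- .colFStat(x, y)
        f_batch <- .colFStat(x, batch)
        confounded <- which(f_batch > f_label)
        keep <- setdiff(surviving, confounded)
        if (length(keep) >= target_k) surviving <- keep
    }
    withr::with_seed(as.integer(seed), {
        folds_idx <- .innerFolds(y, inner_folds)
        while (length(surviving) > target_k) {
            w <- .svmFeatureWeights(x[, surviving, drop = FALSE], y,
                                    folds_idx, C)
            n_drop <- min(max(1L, floor(drop_frac * length(surviving))),
                          length(surviving) - target_k)
            # smallest weights go; ties broken toward higher column index
            drop <- order(w, -surviving)[seq_len(n_drop)]
            surviving <- surviving[-drop]
        }
    })
    sel <- sort(surviving)
    names(sel) <- colnames(x)[sel]
    sel
}

# one-way ANOVA F statistic per column
.colFStat <- function(x, g) {
    g <- factor(g)
    n <- nrow(x)
    k <- nlevels(g)
    gm <- colMeans(x)
    ssb <- numeric(ncol(x))
    ssw <- numeric(ncol(x))
    for (lv in levels(g)) {
        rows <- g == lv
        m <- colMeans(x[rows, , drop = FALSE])
        ssb <- ssb + sum(rows) * (m - gm)^2
        ssw <- ssw + colSums(sweep(x[rows, , drop = FALSE], 2, m)^2)
    }
    (ssb / (k - 1)) / (ssw / (n - k))
}

#' Patient-level evaluation of spectrum predictions
#'
#' Aggregates per-spectrum predictions to one label per patient by majority
#' vote over that patient's technical replicates (ties go to the positive
#' class), builds the patient-level confusion table, and computes
#' `tpr = TP/(TP+FN)`, `tnr = TN/(TN+FP)`, `fpr = 1 - tnr` and
#' `balanced_accuracy = (tpr + tnr)/2` (the last two identities hold exactly
#' by construction).
#'
#' @param predictions per-spectrum predicted labels.
#' @param patient_id patient per spectrum.
#' @param truth true label per spectrum (constant within patient).
#' @param positive the label counted as positive.
#' @param selected_features optional character vector recorded in the report.
#' @param fold optional fold id per spectrum (recorded).
#' @return a [ClassifierReport-class].
#' @export
evaluateClassifier <- function(predictions, patient_id, truth, positive,
                               selected_features = character(0),
                               fold = NA_integer_) {
    .assert(length(predictions) == length(patient_id) &&
            length(truth) == length(patient_id),
            "predictions, patient_id and truth must be aligned")
    predictions <- as.character(predictions)
    truth <- as.character(truth)
    positive <- as.character(positive)
    spec_df <- data.frame(patient_id = as.character(patient_id),
                          truth = truth, predicted = predictions,
                          fold = fold, stringsAsFactors = FALSE)
    agg <- lapply(split(spec_df, spec_df$patient_id), function(d) {
        votes <- table(d$predicted)
        top <- names(votes)[votes == max(votes)]
        lab <- if (positive %in% top) positive else top[1]
        data.frame(patient_id = d$patient_id[1], truth = d$truth[1],
                   predicted = lab, stringsAsFactors = FALSE)
    })
    pat <- do.call(rbind, agg)
    rownames(pat) <- NULL
    is_pos <- pat$truth == positive
    pred_pos <- pat$predicted == positive
    tp <- sum(is_pos & pred_pos); fn <- sum(is_pos & !pred_pos)
    tn <- sum(!is_pos & !pred_pos); fp <- sum(!is_pos & pred_pos)
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    new("ClassifierReport",
        selectedFeatures = as.character(selected_features),
        spectrumPredictions = spec_df, patientPredictions = pat,
        confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
        metrics = c(tpr = tpr, tnr = tnr, fpr = 1 - tnr,
                    balanced_accuracy = (tpr + tnr) / 2),
        positiveClass = positive)
}

#' t-SNE of the refined feature space
#'
#' Embeds the feature-refined matrix (typically 50 retained features) with
#' the clinical t-SNE preset (perplexity 5, learning rate 50, PCA
#' initialisation, 3 dimensions).
#'
#' @param x feature matrix restricted to the selected features (>= 3 columns).
#' @param seed integer seed.
#' @return n x 3 embedding matrix.
#' @export
visualizeRefined <- function(x, seed = 1L) {
    .assert(ncol(x) >= 3, "need at least 3 selected features")
    tsneEmbed(x, preset = "clinical", seed = seed)
}

#' Leave-one-patient-out SVM evaluation
#'
#' The full clinical procedure on a feature table: LOPO folds, per-fold
#' feature refinement on the training patients only (no selection leakage
#' into the held-out patient), linear SVM fit and prediction of the held-out
#' replicates, then patient-level aggregation and metrics. With
#' `refine_once = TRUE` refinement is instead run once on the full data
#' before cross-validation (the optimistic variant some historical workflows
#' used); the leakage-free per-fold mode is the default.
#'
#' @param x feature matrix (spectra x features).
#' @param meta data.frame with columns `patient_id` and `label` (and
#'   optionally `batch`) aligned with `x`.
#' @param positive label counted as positive; defaults to the
#'   lexicographically last label.
#' @param target_k refined feature-set size (default 50); NULL disables
#'   refinement.
#' @param use_batch use `meta$batch` in the refinement confounder filter.
#' @param C SVM penalty.
#' @param refine_once refine on the full data instead of per fold.
#' @param seed integer seed.
#' @return a [ClassifierReport-class]; the recorded `selectedFeatures` come
#'   from a refinement on the full data (the set used for visualization).
#' @export
lopoEvaluate <- function(x, meta, positive = NULL, target_k = 50,
                         use_batch = FALSE, C = 1, refine_once = FALSE,
                         seed = 1L) {
    x <- as.matrix(x)
    .assert(all(c("patient_id", "label") %in% colnames(meta)),
            "meta needs patient_id and label columns")
    y <- as.character(meta$label)
    if (is.null(positive)) positive <- max(y)
    batch <- if (use_batch && "batch" %in% colnames(meta)) meta$batch else NULL
    folds <- lopoFolds(meta$patient_id, y)

    global_sel <- if (!is.null(target_k))
        refineFeatures(x, y, batch = batch, target_k = target_k, C = C,
                       seed = seed)
    else seq_len(ncol(x))

    pred <- character(nrow(x))
    fold_id <- integer(nrow(x))
    for (i in seq_along(folds)) {
        f <- folds[[i]]
        sel <- if (is.null(target_k)) seq_len(ncol(x))
               else if (refine_once) global_sel
               else refineFeatures(x[f$train, , drop = FALSE], y[f$train],
                                   batch = batch[f$train],
                                   target_k = target_k, C = C,
                                   seed = .childSeed(seed, f$patient))
        pred[f$test] <- fitPredictSVM(x[f$train, sel, drop = FALSE],
                                      y[f$train],
                                      x[f$test, sel, drop = FALSE], C = C)
        fold_id[f$test] <- i
    }
    evaluateClassifier(pred, meta$patient_id, y, positive,
                       selected_features = if (!is.null(colnames(x)))
                           colnames(x)[global_sel] else as.character(global_sel),
                       fold = fold_id)
}
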