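# Semi-supervised wrapper: stratified split, nested cross-validation over
# the number of top-ranked islands, classifier construction, prediction.

#' Stratified 2:1 train/test split
#'
#' Within each case stratum, `floor(stratum size x trainFraction)` samples
#' are drawn uniformly (given `seed`) into the training set; the remainder
#' form the testing set. The partition is disjoint and exhaustive.
#'
#' @param ss sample-sheet data.frame.
#' @param trainFraction training fraction; default 2/3.
#' @param seed integer seed.
#' @return `ss` with a `split` column ("train"/"test").
#' @export
stratifiedSplit <- function(ss, trainFraction = 2 / 3, seed = 1L) {
    ss <- validateSampleSheet(ss)
    set.seed(as.integer(seed))
    ss$split <- NA_character_
    for (lev in sort(unique(ss$case))) {
        idx <- which(ss$case == lev)
        if (length(idx) < 3L)
            stop("case stratum ", lev, " has fewer than 3 samples")
        nTrain <- floor(length(idx) * trainFraction)
        tr <- sample(idx, nTrain)
        ss$split[tr] <- "train"
        ss$split[setdiff(idx, tr)] <- "test"
    }
    ss
}

# Stratified fold labels in 1..nFolds, balanced within each case stratum.
.stratifiedFolds <- function(case, nFolds, seed) {
    set.seed(as.integer(seed))
    folds <- integer(length(case))
    for (lev in sort(unique(case))) {
        idx <- which(case == lev)
        folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    folds
}

# Held-out association between hard class labels and case status:
# chi-square statistic of the class x case table (0 when degenerate).
.classCaseChisq <- function(labels, case) {
    tab <- table(labels, case)
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
    out <- tryCatch(
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)),
        error = function(e) NULL)
    if (is.null(out) || !is.finite(out$statistic)) 0
    else unname(out$statistic)
}

#' Select the number of classifier islands by nested cross-validation
#'
#' Stratified folds are drawn within the training set. In each fold the
#' islands are re-ranked on the fold's training portion only (no information
#' from held-out samples enters the ranking), an RPMM is fitted to the
#' top-m islands for every candidate m, held-out samples are assigned to
#' classes via the empirical Bayes posterior, and the held-out association
#' between hard class label and case status is scored by the chi-square
#' statistic of the class x case table. The objective for each m is the sum
#' of fold scores; the selected M is its argmax, with ties going to the
#' smallest m (parsimony).
#'
#' @param imTrain [IslandMatrix-class] of training samples.
#' @param ssTrain sample sheet of training samples.
#' @param mGrid candidate island counts (>= 2, <= number of islands);
#'   default `2:min(50, nIslands)`.
#' @param nFolds number of folds; default 10.
#' @param seed integer seed.
#' @param minClassSize,maxDepth forwarded to [fitRPMM()].
#' @return list with `m` (selected M) and `trace` (data.frame of `m` and
#'   summed `objective`).
#' @export
nestedCVSelectM <- function(imTrain, ssTrain, mGrid = NULL, nFolds = 10L,
                            seed = 1L, minClassSize = 5, maxDepth = 6L) {
    stopifnot(is(imTrain, "IslandMatrix"))
    ssTrain <- validateSampleSheet(ssTrain)
    nIsl <- nrow(imTrain)
    if (is.null(mGrid)) mGrid <- 2:min(50L, nIsl)
    mGrid <- sort(unique(as.integer(mGrid)))
    if (any(mGrid < 2L) || any(mGrid > nIsl))
        stop("mGrid values must be in [2, number of islands]")
    if (nFolds < 2L) stop("nFolds must be >= 2")
    keep <- match(ssTrain$sample_id, colnames(avgBeta(imTrain)))
    if (anyNA(keep)) stop("sample sheet and island matrix do not match")
    b <- avgBeta(imTrain)[, ssTrain$sample_id, drop = FALSE]

    folds <- .stratifiedFolds(ssTrain$case, nFolds, seed)
    obj <- stats::setNames(numeric(length(mGrid)), mGrid)
    for (f in seq_len(nFolds)) {
        inIdx <- which(folds != f)
        outIdx <- which(folds == f)
        ssIn <- ssTrain[inIdx, , drop = FALSE]
        imIn <- IslandMatrix(b[, inIdx, drop = FALSE],
                             ranges = rowRanges(imTrain),
                             nProbes = rowData(imTrain)$nProbes)
        ranked <- rankIslands(imIn, ssIn, trainingOnly = FALSE)
        for (g in seq_along(mGrid)) {
            m <- mGrid[g]
            ids <- ranked$island_id[seq_len(m)]
            xIn <- t(b[ids, inIdx, drop = FALSE])
            model <- fitRPMM(xIn, minClassSize = minClassSize,
                             maxDepth = maxDepth,
                             seed = .deriveSeed(seed, paste0("fold", f)))
            xOut <- t(b[ids, outIdx, drop = FALSE])
            pred <- posteriorClasses(model, xOut)
            obj[g] <- obj[g] +
                .classCaseChisq(pred$classes, ssTrain$case[outIdx])
        }
    }
    trace <- data.frame(m = mGrid, objective = unname(obj))
    list(m = mGrid[which.max(obj)], trace = trace)
}

#' Build the island methylation classifier
#'
#' Fits the RPMM to the training samples on the top-m ranked islands. The
#' RPMM consumes raw beta values in \[0, 1\] (the logit transform is used
#' only for the ranking stage's linear models).
#'
#' @param imTrain [IslandMatrix-class].
#' @param ssTrain training sample sheet (if a `split` column is present only
#'   `split == "train"` rows are used).
#' @param ranked ranking data.frame from [rankIslands()].
#' @param m number of top islands to use.
#' @param seed integer seed for the RPMM fit.
#' @param minClassSize,maxDepth forwarded to [fitRPMM()].
#' @param cvTrace optional cross-validation trace to store.
#' @return a [ClassifierSpec-class]
#' @export
buildClassifier <- function(imTrain, ssTrain, ranked, m, seed = 1L,
                            minClassSize = 5, maxDepth = 6L,
                            cvTrace = NULL) {
    stopifnot(is(imTrain, "IslandMatrix"))
    if (m > nrow(ranked)) stop("m exceeds the number of ranked islands")
    ssTrain <- validateSampleSheet(ssTrain)
    if ("split" %in% names(ssTrain))
        ssTrain <- ssTrain[!is.na(ssTrain$split) & ssTrain$split == "train", ,
                           drop = FALSE]
    ids <- ranked$island_id[seq_len(m)]
    x <- t(avgBeta(imTrain)[ids, ssTrain$sample_id, drop = FALSE])
    model <- fitRPMM(x, minClassSize = minClassSize, maxDepth = maxDepth,
                     seed = seed)
    new("ClassifierSpec", mSelected = as.integer(m), islandIds = ids,
        model = model,
        cvTrace = if (is.null(cvTrace))
            data.frame(m = integer(0), objective = numeric(0))
        else as.data.frame(cvTrace))
}

#' Predict methylation classes for new samples
#'
#' Applies the latent class structure of the training fit to new samples via
#' the empirical Bayes posterior ([posteriorClasses()]).
#'
#' @param spec a [ClassifierSpec-class]
#' @param imTest [IslandMatrix-class] containing all classifier islands.
#' @return list with `posterior` (samples x classes) and `classes` (hard
#'   labels), ordered as the columns of `imTest`.
#' @export
predictClasses <- function(spec, imTest) {
    stopifnot(is(spec, "ClassifierSpec"), is(imTest, "IslandMatrix"))
    missingIsl <- setdiff(spec@islandIds, rownames(imTest))
    if (length(missingIsl))
        stop("island(s) missing from test data: ",
             paste(missingIsl, collapse = ", "))
    x <- t(avgBeta(imTest)[spec@islandIds, , drop = FALSE])
    posteriorClasses(spec@model, x)
}

#' Serialize a classifier to JSON
#'
#' @param spec a [ClassifierSpec-class]
#' @param path output JSON path.
#' @return invisibly, `path`; [readClassifier()] restores a spec producing
#'   identical predictions.
#' @export
writeClassifier <- function(spec, path) {
    obj <- list(mSelected = spec@mSelected, islandIds = spec@islandIds,
                cvTrace = spec@cvTrace,
                model = list(featureIds = spec@model@featureIds,
                             tree = .nodeToList(spec@model@root)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    root <- .nodeFromList(
        jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)$model$tree)
    leaves <- .collectLeaves(root)
    nms <- vapply(leaves, `[[`, character(1), "name")
    model <- new("RPMMModel", root = root,
                 featureIds = as.character(obj$model$featureIds),
                 terminalClasses = nms,
                 trainPosteriors = matrix(numeric(0), 0, length(nms),
                                          dimnames = list(NULL, nms)))
    cv <- if (is.null(obj$cvTrace) || !length(obj$cvTrace))
        data.frame(m = integer(0), objective = numeric(0))
    else as.data.frame(obj$cvTrace)
    new("ClassifierSpec", mSelected = as.integer(obj$mSelected),
        islandIds = as.character(obj$islandIds), model = model,
        cvTrace = cv)
}
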