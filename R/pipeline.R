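# End-to-end orchestration: simulate/read -> aggregate -> split -> rank ->
# select M -> fit -> predict -> evaluate (-> paired validation), with every
# artifact written to a run directory and a manifest of parameters, seed and
# file hashes. Identical configuration reproduces identical artifacts.

#' Identify case-heavy classes from training labels
#'
#' Classes whose training-set case fraction is at least `threshold` are
#' treated as predicted-positive downstream. Chosen on training data only,
#' so test-set evaluation stays leakage-free. May return an empty set.
#'
#' @param labels character vector of training hard class labels.
#' @param case 0/1 case indicator aligned with `labels`.
#' @param threshold minimum case fraction; default 0.8.
#' @return character vector of class names.
#' @export
autoPositiveClasses <- function(labels, case, threshold = 0.8) {
    if (!length(labels)) stop("need at least one class label")
    frac <- tapply(case, labels, mean)
    names(frac)[frac >= threshold]
}

# Posterior-weighted class case-probability score: the training case
# fraction of each class (posterior-weighted), mapped onto new samples
# through their class posteriors.
.classCaseScore <- function(postTrain, caseTrain, postNew) {
    num <- colSums(postTrain * caseTrain)
    den <- colSums(postTrain)
    frac <- ifelse(den > 0, num / den, mean(caseTrain))
    drop(postNew %*% frac[colnames(postNew)])
}

.defaultPipelineConfig <- function() {
    list(minProbes = 3L, epsilon = 1e-6, trainFraction = 2 / 3,
         mGrid = NULL, nFolds = 10L, minClassSize = 5, maxDepth = 6L,
         positiveClasses = "auto", positiveThreshold = 0.8,
         qThreshold = 0.05, seed = 1L, paired = NULL, outDir = NULL)
}

#' Run the full classifier pipeline
#'
#' Executes, in order: data input (either a synthetic cohort via
#' `config$simulate`, a list of [syntheticConfig()] arguments, or the three
#' file paths `probePath`/`annotationPath`/`samplePath`), probe filtering,
#' island aggregation, stratified 2:1 split (skipped when the sample sheet
#' already carries a `split` column), training-set island ranking, nested
#' cross-validation over `mGrid` (skipped for a single candidate), classifier
#' construction, test-set class prediction, case-heavy class selection on
#' training labels, and evaluation (confusion table, exact and logistic odds
#' ratios, ROC/AUC of the posterior-weighted class case-probability score).
#' When `config$paired` is a list (fields `nPairs`, `islandDeltas`,
#' `precision`), a paired tumor/normal validation stage is run on synthetic
#' pairs. All stages are seeded from `config$seed`; re-running an identical
#' configuration reproduces identical artifacts.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized fields beyond the above: `minProbes`, `epsilon`,
#'   `trainFraction`, `nFolds`, `minClassSize`, `maxDepth`,
#'   `positiveClasses` ("auto" or explicit class names),
#'   `positiveThreshold`, `qThreshold`, `seed`, `outDir`.
#' @return invisibly, the summary list (also written to
#'   `outDir/summary.json` when `outDir` is set).
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    cfg <- utils::modifyList(.defaultPipelineConfig(), config)
    seed <- as.integer(cfg$seed)
    outDir <- cfg$outDir
    if (!is.null(outDir))
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    emit <- function(name, writer) {
        if (!is.null(outDir)) writer(file.path(outDir, name))
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    # --- input ---------------------------------------------------------
    if (!is.null(cfg$simulate)) {
        simArgs <- cfg$simulate
        if (is.null(simArgs$seed)) simArgs$seed <- seed
        ds <- stage("simulate",
                    simulateCohort(do.call(syntheticConfig, simArgs)))
    } else {
        for (p in c("probePath", "annotationPath", "samplePath"))
            if (is.null(cfg[[p]]))
                stop("config must provide 'simulate' or the three input paths")
        ds <- stage("read", readMethylDataset(
            cfg$probePath, cfg$annotationPath, cfg$samplePath,
            probeMetaPath = cfg$probeMetaPath,
            detectionPath = cfg$detectionPath))
    }
    ss <- ds$samples

    # --- aggregate -----------------------------------------------------
    im <- stage("aggregate", {
        pm <- filterProbes(ds$probes)
        aggregateIslands(pm, ds$annotation, minProbes = cfg$minProbes)
    })

    # --- split ---------------------------------------------------------
    if (!"split" %in% names(ss))
        ss <- stage("split", stratifiedSplit(ss, cfg$trainFraction, seed))
    emit("sample_sheet.csv", function(p)
        utils::write.csv(ss, p, row.names = FALSE, quote = FALSE))
    ssTrain <- ss[ss$split == "train", , drop = FALSE]
    ssTest <- ss[ss$split == "test", , drop = FALSE]

    # --- rank ----------------------------------------------------------
    ranked <- stage("rank", rankIslands(im, ss, trainingOnly = TRUE,
                                        epsilon = cfg$epsilon))
    emit("ranking.tsv", function(p)
        utils::write.table(ranked, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))

    # --- select M ------------------------------------------------------
    imTrain <- IslandMatrix(avgBeta(im)[, ssTrain$sample_id, drop = FALSE],
                            ranges = rowRanges(im),
                            nProbes = rowData(im)$nProbes)
    mGrid <- cfg$mGrid
    if (is.null(mGrid)) mGrid <- 2:min(50L, nrow(im))
    if (length(mGrid) > 1L) {
        sel <- stage("select_m", nestedCVSelectM(
            imTrain, ssTrain, mGrid = mGrid, nFolds = cfg$nFolds,
            seed = seed, minClassSize = cfg$minClassSize,
            maxDepth = cfg$maxDepth))
        m <- sel$m; cvTrace <- sel$trace
    } else {
        m <- as.integer(mGrid)
        cvTrace <- data.frame(m = m, objective = NA_real_)
    }
    emit("cv_trace.tsv", function(p)
        utils::write.table(cvTrace, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))

    # --- train / predict -----------------------------------------------
    spec <- stage("train", buildClassifier(
        imTrain, ssTrain, ranked, m, seed = seed,
        minClassSize = cfg$minClassSize, maxDepth = cfg$maxDepth,
        cvTrace = cvTrace))
    emit("classifier.json", function(p) writeClassifier(spec, p))
    imTest <- IslandMatrix(avgBeta(im)[, ssTest$sample_id, drop = FALSE],
                           ranges = rowRanges(im),
                           nProbes = rowData(im)$nProbes)
    predTrain <- stage("predict", predictClasses(spec, imTrain))
    predTest <- stage("predict", predictClasses(spec, imTest))
    emit("predictions_test.tsv", function(p) {
        out <- data.frame(sample_id = ssTest$sample_id,
                          class = predTest$classes,
                          predTest$posterior, check.names = FALSE)
        utils::write.table(out, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    })

    # --- evaluate ------------------------------------------------------
    summary <- stage("evaluate", {
        positive <- cfg$positiveClasses
        if (identical(positive, "auto"))
            positive <- autoPositiveClasses(predTrain$classes, ssTrain$case,
                                            cfg$positiveThreshold)
        scoreTest <- .classCaseScore(predTrain$posterior, ssTrain$case,
                                     predTest$posterior)
        roc <- rocAuc(scoreTest, ssTest$case)
        emit("roc_points.tsv", function(p)
            utils::write.table(roc$curve, p, sep = "\t", quote = FALSE,
                               row.names = FALSE))
        res <- list(selected_m = m,
                    n_classes = length(terminalClasses(spec)),
                    classes = terminalClasses(spec),
                    positive_classes = positive,
                    auc = roc$auc, auc_ci = c(roc$ci_low, roc$ci_high))
        if (length(positive)) {
            conf <- confusionFromClasses(predTest$classes, ssTest$case,
                                         positive)
            orres <- fisherExactOR(matrix(
                c(conf$tp, conf$fn, conf$fp, conf$tn), 2L, 2L))
            memb <- as.numeric(predTest$classes %in% positive)
            logit <- if (length(unique(memb)) > 1L)
                logisticModel(ssTest$case, data.frame(member = memb))
            else NULL
            res$confusion <- conf
            res$or_cmle <- orres$or_cmle
            res$or_ci <- c(orres$ci_low, orres$ci_high)
            res$or_crossprod <- orres$or_crossprod
            if (!is.null(logit))
                res$or_logistic <- logit$coefficients$or[
                    logit$coefficients$term == "member"]
        }
        res
    })

    # --- paired validation ---------------------------------------------
    if (is.list(cfg$paired)) {
        pr <- cfg$paired
        summary$paired <- stage("diffmeth", {
            sim <- simulatePairs(pr$nPairs, unlist(pr$islandDeltas),
                                 precision = if (is.null(pr$precision)) 100
                                 else pr$precision,
                                 seed = seed)
            res <- pairedIslandTest(sim$tumor, sim$normal, sim$pairing)
            emit("paired_diffmeth.tsv", function(p)
                utils::write.table(res, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE))
            list(n_islands = nrow(res),
                 n_significant = countSignificant(res, cfg$qThreshold))
        })
    }

    emit("summary.json", function(p)
        jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE))
    if (!is.null(outDir)) {
        arts <- setdiff(list.files(outDir), "manifest.json")
        manifest <- list(
            seed = seed,
            parameters = cfg[setdiff(names(cfg), c("outDir"))],
            artifacts = as.list(tools::md5sum(file.path(outDir, arts))))
        names(manifest$artifacts) <- arts
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(summary)
}
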