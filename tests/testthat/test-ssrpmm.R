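.sheet <- function(nCase, nControl) {
    n <- nCase + nControl
    data.frame(sample_id = sprintf("s%02d", seq_len(n)),
               case = rep(c(1L, 0L), c(nCase, nControl)),
               age = 60, sex = 1, pack_years = 0, alcohol = 0,
               batch = "B1", stringsAsFactors = FALSE)
}

test_that("stratified split honours the 2:1 ratio within strata", {
    ss <- stratifiedSplit(.sheet(9, 6), seed = 1)
    tab <- table(ss$case, ss$split)
    expect_identical(unname(tab["1", "train"]), 6L)
    expect_identical(unname(tab["1", "test"]), 3L)
    expect_identical(unname(tab["0", "train"]), 4L)
    expect_identical(unname(tab["0", "test"]), 2L)

    ss2 <- stratifiedSplit(.sheet(9, 6), seed = 1)
    expect_identical(ss, ss2)                       # seeded reproducibility
    expect_false(any(is.na(ss$split)))              # exhaustive partition
    expect_error(stratifiedSplit(.sheet(9, 2)), "fewer than 3")
})

test_that("singleton m grids pass through the nested CV untouched", {
    cohort <- makeCohort(nCases = 40, nControls = 26, nIslands = 30,
                         nInformative = 6, seed = 31)
    sel <- nestedCVSelectM(cohort$im, cohort$samples, mGrid = 22,
                           nFolds = 3, seed = 1)
    expect_identical(sel$m, 22L)
    expect_identical(nrow(sel$trace), 1L)
    expect_error(nestedCVSelectM(cohort$im, cohort$samples, mGrid = 1),
                 "mGrid")
})

test_that("classifier construction recovers planted class structure", {
    pat <- cbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))  # 2 islands x 4 classes
    pat <- pat[rep(1:2, 3), ]                         # 6 informative islands
    cohort <- makeCohort(nCases = 120, nControls = 80, nIslands = 40,
                         nInformative = 6, effectDelta = 0.35,
                         precision = 100, classPatterns = pat,
                         classWeights = rep(0.25, 4), seed = 33)
    ss <- cohort$samples
    ss$split <- "train"
    # hand the planted islands to the builder directly: this exercises the
    # RPMM construction, not the outcome-guided ranking (which has no reason
    # to surface class contrasts orthogonal to case status)
    inf <- sort(cohort$truth$informativeIslandIds)
    ranked <- data.frame(island_id = inf, t_stat = 0, abs_t = 0,
                         rank = seq_along(inf), flag = "ok")
    spec <- buildClassifier(cohort$im, ss, ranked, m = 6, seed = 1)
    expect_identical(length(terminalClasses(spec)), 4L)
    pred <- predictClasses(spec, cohort$im)
    expect_gte(adjRandIndex(pred$classes, cohort$truth$classLabel), 0.9)

    specMin <- buildClassifier(cohort$im, ss, ranked, m = 2, seed = 1)
    expect_gte(length(terminalClasses(specMin)), 2L)
    expect_identical(specMin@mSelected, 2L)
})

test_that("prediction enforces the island contract and normalization", {
    cohort <- makeCohort(nCases = 40, nControls = 26, nIslands = 20,
                         nInformative = 4, seed = 35)
    ss <- cohort$samples
    ss$split <- "train"
    ranked <- rankIslands(cohort$im, ss)
    spec <- buildClassifier(cohort$im, ss, ranked, m = 4, seed = 1)
    pred <- predictClasses(spec, cohort$im)
    expect_equal(unname(rowSums(pred$posterior)),
                 rep(1, ncol(avgBeta(cohort$im))),
                 tolerance = 1e-8)
    imDropped <- IslandMatrix(
        avgBeta(cohort$im)[setdiff(rownames(cohort$im), spec@islandIds[1]), ])
    expect_error(predictClasses(spec, imDropped), spec@islandIds[1],
                 fixed = TRUE)
})

test_that("classifier JSON round-trips with identical predictions", {
    cohort <- makeCohort(nCases = 40, nControls = 26, nIslands = 20,
                         nInformative = 4, seed = 37)
    ss <- cohort$samples
    ss$split <- "train"
    ranked <- rankIslands(cohort$im, ss)
    spec <- buildClassifier(cohort$im, ss, ranked, m = 5, seed = 2,
                            cvTrace = data.frame(m = 5, objective = 1.5))
    path <- withr::local_tempfile(fileext = ".json")
    writeClassifier(spec, path)
    back <- readClassifier(path)
    expect_identical(back@mSelected, spec@mSelected)
    expect_identical(back@islandIds, spec@islandIds)
    p1 <- predictClasses(spec, cohort$im)
    p2 <- predictClasses(back, cohort$im)
    expect_equal(p1$posterior, p2$posterior, tolerance = 1e-12)
    expect_identical(p1$classes, p2$classes)
})

test_that("test-set beta values never leak into training decisions", {
    cohort <- makeCohort(nCases = 60, nControls = 40, nIslands = 40,
                         nInformative = 8, seed = 39)
    ss <- stratifiedSplit(cohort$samples, seed = 39)
    ssTrain <- ss[ss$split == "train", ]
    b <- avgBeta(cohort$im)

    run <- function(bMat) {
        im <- IslandMatrix(bMat)
        imTrain <- IslandMatrix(bMat[, ssTrain$sample_id, drop = FALSE])
        ranked <- rankIslands(im, ss, trainingOnly = TRUE)
        sel <- nestedCVSelectM(imTrain, ssTrain, mGrid = c(3, 6),
                               nFolds = 3, seed = 7)
        spec <- buildClassifier(imTrain, ssTrain, ranked, sel$m, seed = 7)
        list(ranked = ranked, sel = sel, spec = spec)
    }
    clean <- run(b)
    poisoned <- b
    testIds <- ss$sample_id[ss$split == "test"]
    set.seed(123)
    poisoned[, testIds] <- matrix(runif(nrow(b) * length(testIds)),
                                  nrow(b), length(testIds))
    dirty <- run(poisoned)
    expect_identical(clean$ranked, dirty$ranked)
    expect_identical(clean$sel, dirty$sel)
    expect_identical(clean$spec@islandIds, dirty$spec@islandIds)
    expect_identical(clean$spec@model@root, dirty$spec@model@root)
})
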