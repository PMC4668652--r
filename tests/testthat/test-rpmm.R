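test_that("weighted beta fit starts at the method of moments and improves it", {
    mom <- ssRPMM:::.momBeta(0.5, 1 / 12)
    expect_equal(unname(mom), c(1, 1))            # uniform moments -> Beta(1,1)

    set.seed(1)
    x <- runif(5000)
    fit <- weightedBetaFit(x)
    expect_equal(fit$a, 1, tolerance = 0.1)
    expect_equal(fit$b, 1, tolerance = 0.1)

    # equal weights match the unweighted fit
    fitW <- weightedBetaFit(x, rep(2.5, length(x)))
    expect_equal(fit$a, fitW$a, tolerance = 1e-8)
    expect_equal(fit$b, fitW$b, tolerance = 1e-8)
})

test_that("beta parameters are recovered within 5% at n = 10000", {
    set.seed(42)
    x <- rbeta(10000, 5, 2)
    fit <- weightedBetaFit(x)
    expect_lt(abs(fit$a - 5) / 5, 0.05)
    expect_lt(abs(fit$b - 2) / 2, 0.05)
})

test_that("overdispersed data fall back to unit concentration", {
    x <- c(rep(0, 10), rep(1, 10))      # v ~ m(1-m): beyond beta support
    fit <- weightedBetaFit(x)
    expect_identical(fit$method, "moments")
    expect_equal(fit$a + fit$b, 2, tolerance = 1e-8)
    expect_error(weightedBetaFit(rep(0.5, 10)), "distinct")
})

test_that("product-beta log-likelihood matches closed forms and clamps", {
    x <- matrix(runif(12), 4, 3)
    expect_equal(betaLoglik(x, list(a = rep(1, 3), b = rep(1, 3))),
                 rep(0, 4))
    expect_equal(betaLoglik(matrix(0.5), list(a = 2, b = 2)), log(1.5))
    ll0 <- betaLoglik(matrix(0), list(a = 2, b = 2))
    expect_true(is.finite(ll0))
    expect_equal(ll0, dbeta(1e-6, 2, 2, log = TRUE))
    expect_error(betaLoglik(x, list(a = 1, b = 1)), "match")
})

test_that("two-class EM separates planted clusters and is monotone", {
    pl <- plantedBetaClasses(n = 100, p = 8, K = 2, conc = 100, seed = 3,
                             minSep = 0.3)
    em <- emTwoClass(pl$x, seed = 1)
    hard <- max.col(em$resp)
    expect_equal(adjRandIndex(hard, pl$labels), 1.0)
    expect_true(all(diff(em$loglikTrace) >= -1e-8 *
                        (abs(em$loglikTrace[-length(em$loglikTrace)]) + 1)))
    expect_equal(unname(rowSums(em$resp)), rep(1, 100), tolerance = 1e-8)
})

test_that("the BIC gate accepts only real likelihood gains", {
    eq <- splitDecision(-100, -100, nEffective = 50, nFeatures = 10)
    expect_false(eq$accept)
    big <- splitDecision(-1000, 0, nEffective = 10, nFeatures = 5)
    expect_true(big$accept)                       # gain 1000 >> penalty

    # single-cluster data: splits rejected in >= 90% of seeds
    rejected <- 0
    nSeeds <- 50
    for (s in seq_len(nSeeds)) {
        pl <- plantedBetaClasses(n = 200, p = 20, K = 1, conc = 30,
                                 seed = 100 + s)
        one <- ssRPMM:::.fitNodeParams(pl$x, rep(1, 200))
        em <- emTwoClass(pl$x, seed = s)
        dec <- splitDecision(one$loglik, em$loglik, 200, 20)
        if (!dec$accept || em$degenerate) rejected <- rejected + 1
    }
    expect_gte(rejected / nSeeds, 0.9)
})

test_that("RPMM recovers planted class structure with dendrogram naming", {
    pl <- plantedBetaClasses(n = 200, p = 22, K = 4, conc = 100, seed = 7)
    model <- fitRPMM(pl$x, seed = 1)
    expect_identical(length(terminalClasses(model)), 4L)
    hard <- terminalClasses(model)[max.col(model@trainPosteriors)]
    expect_gte(adjRandIndex(hard, pl$labels), 0.9)
    expect_true(all(grepl("^r[LR]+$", terminalClasses(model))))
    # left-to-right traversal is lexicographic for an antichain of names
    expect_identical(terminalClasses(model),
                     sort(terminalClasses(model)))
    if (requireNamespace("mclust", quietly = TRUE))
        expect_gte(mclust::adjustedRandIndex(hard, pl$labels), 0.9)
})

test_that("homogeneous data yield the single root class", {
    pl <- plantedBetaClasses(n = 150, p = 10, K = 1, conc = 40, seed = 9)
    model <- fitRPMM(pl$x, seed = 1)
    expect_identical(terminalClasses(model), "r")
    expect_equal(model@root$weight, 1)
})

test_that("RPMM fits are invariant to sample order", {
    pl <- plantedBetaClasses(n = 120, p = 10, K = 3, conc = 80, seed = 11)
    m1 <- fitRPMM(pl$x, seed = 5)
    perm <- sample(nrow(pl$x))
    m2 <- fitRPMM(pl$x[perm, ], seed = 5)
    expect_identical(terminalClasses(m1), terminalClasses(m2))
    l1 <- ssRPMM:::.collectLeaves(m1@root)
    l2 <- ssRPMM:::.collectLeaves(m2@root)
    for (k in seq_along(l1)) {
        expect_equal(l1[[k]]$a, l2[[k]]$a, tolerance = 1e-6)
        expect_equal(l1[[k]]$weight, l2[[k]]$weight, tolerance = 1e-8)
    }
    expect_equal(m1@trainPosteriors[perm, ], m2@trainPosteriors,
                 tolerance = 1e-6)
})

test_that("two-class mixtures are recovered to within 0.05 in the means", {
    set.seed(13)
    p <- 6
    mA <- runif(p, 0.2, 0.4); mB <- mA + 0.25
    cls <- rep(1:2, each = 250)
    means <- rbind(mA, mB)[cls, ]
    x <- matrix(rbeta(500 * p, means * 50, (1 - means) * 50), 500, p)
    colnames(x) <- sprintf("f%d", 1:p)
    model <- fitRPMM(x, seed = 2)
    expect_identical(length(terminalClasses(model)), 2L)
    leaves <- ssRPMM:::.collectLeaves(model@root)
    fitMeans <- t(vapply(leaves, function(l) l$a / (l$a + l$b), numeric(p)))
    # match leaves to planted classes by first feature
    ord <- order(fitMeans[, 1])
    expect_lt(max(abs(fitMeans[ord[1], ] - mA)), 0.05)
    expect_lt(max(abs(fitMeans[ord[2], ] - mB)), 0.05)
})

test_that("posterior class assignment is normalized, centroid-consistent and stable", {
    pl <- plantedBetaClasses(n = 200, p = 12, K = 3, conc = 100, seed = 15)
    model <- fitRPMM(pl$x, seed = 3)
    post <- posteriorClasses(model, pl$x)
    expect_equal(unname(rowSums(post$posterior)), rep(1, 200), tolerance = 1e-8)

    # class centroids are assigned to their own class
    leaves <- ssRPMM:::.collectLeaves(model@root)
    centroids <- t(vapply(leaves, function(l) l$a / (l$a + l$b),
                          numeric(ncol(pl$x))))
    colnames(centroids) <- colnames(pl$x)
    cpost <- posteriorClasses(model, centroids)
    expect_identical(cpost$classes, terminalClasses(model))

    # re-scored training samples agree with training fuzzy argmax
    trainHard <- terminalClasses(model)[max.col(model@trainPosteriors)]
    expect_gte(mean(post$classes == trainHard), 0.95)

    expect_error(posteriorClasses(model, pl$x[, -1]), "missing")
})

test_that("model JSON round-trips with identical predictions", {
    pl <- plantedBetaClasses(n = 80, p = 6, K = 2, conc = 80, seed = 19)
    model <- fitRPMM(pl$x, seed = 1)
    path <- withr::local_tempfile(fileext = ".json")
    writeRPMM(model, path)
    back <- readRPMM(path)
    expect_identical(terminalClasses(back), terminalClasses(model))
    p1 <- posteriorClasses(model, pl$x)
    p2 <- posteriorClasses(back, pl$x)
    expect_equal(p1$posterior, p2$posterior, tolerance = 1e-12)
    expect_identical(p1$classes, p2$classes)
})
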