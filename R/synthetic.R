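# Synthetic cohorts with planted latent methylation classes.
#
# The generator mirrors the statistical structure the analysis assumes:
# samples carry a latent class; case status is Bernoulli with a
# class-specific probability (so classes can be case-heavy); a small set of
# informative islands shifts its class-conditional mean beta; island values
# are beta-distributed with a common concentration; probes scatter around
# their island value; a batch label adds an M-scale shift.

#' Synthetic cohort configuration
#'
#' Defaults emulate an oral-rinse 450K case/control study: 152 cases and 71
#' controls; four latent methylation classes with weights (.30, .25, .25,
#' .20) and case probabilities (.97, .92, .35, .15), so the first two classes
#' are case-heavy and the overall case fraction is about 0.64; 300 autosomal
#' islands of which 20 are informative with block-shift deltas of
#' alternating sign and magnitudes 0.10-0.30; island-level beta concentration
#' 50; 4 probes per island with scatter sd 0.02; three processing batches
#' with an additive M-value shift of 0.15 between adjacent batches.
#'
#' `effectDelta` is the difference in mean beta between the case-heavy class
#' block (classes with `classCaseProbs >= 0.8` by default) and the remaining
#' classes on each informative island; scalars are recycled. To plant more
#' than two distinguishable mean profiles, pass `classPatterns`, a 0/1 matrix
#' (informative islands x classes) saying which classes are shifted on each
#' island (default: the case-heavy block on every informative island).
#'
#' @param nCases,nControls target case/control totals; the realized counts
#'   are stochastic because case status is drawn per sample from its class's
#'   case probability (totals `nCases + nControls` samples are generated).
#' @param nIslands,nInformative island counts; `nInformative <= nIslands`.
#' @param nClasses number of latent classes (>= 2).
#' @param classWeights latent class prior weights (normalized internally).
#' @param classCaseProbs per-class probability that a member is a case.
#' @param effectDelta per-informative-island mean-beta shift (scalar
#'   recycled; signs allowed).
#' @param precision beta concentration a+b of island-level values.
#' @param nProbesPerIsland probes per island (>= 3 to survive default
#'   aggregation).
#' @param probeSd sd of probe scatter around the island value (beta scale,
#'   clipped to \[0, 1\]).
#' @param batchLevels number of processing batches (round-robin assignment).
#' @param batchShift additive M-value shift between adjacent batches.
#' @param classPatterns optional 0/1 matrix, nInformative x nClasses.
#' @param ageCaseShift additive shift of mean age for cases (confounding
#'   knob; default 0 keeps covariates independent of class and status).
#' @param seed integer seed.
#' @return a validated configuration list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nCases = 152L, nControls = 71L,
                            nIslands = 300L, nInformative = 20L,
                            nClasses = 4L,
                            classWeights = c(0.30, 0.25, 0.25, 0.20),
                            classCaseProbs = c(0.97, 0.92, 0.35, 0.15),
                            effectDelta = rep(c(1, -1),
                                length.out = nInformative) *
                                seq(0.30, 0.10, length.out = nInformative),
                            precision = 50,
                            nProbesPerIsland = 4L, probeSd = 0.02,
                            batchLevels = 3L, batchShift = 0.15,
                            classPatterns = NULL,
                            ageCaseShift = 0, seed = 1L) {
    cfg <- list(nCases = as.integer(nCases), nControls = as.integer(nControls),
                nIslands = as.integer(nIslands),
                nInformative = as.integer(nInformative),
                nClasses = as.integer(nClasses),
                classWeights = classWeights / sum(classWeights),
                classCaseProbs = classCaseProbs,
                effectDelta = rep_len(effectDelta, nInformative),
                precision = precision,
                nProbesPerIsland = as.integer(nProbesPerIsland),
                probeSd = probeSd, batchLevels = as.integer(batchLevels),
                batchShift = batchShift, classPatterns = classPatterns,
                ageCaseShift = ageCaseShift, seed = as.integer(seed))
    if (cfg$nInformative > cfg$nIslands)
        stop("nInformative must not exceed nIslands")
    if (cfg$nClasses < 2L)
        stop("nClasses must be >= 2")
    if (length(cfg$classWeights) != cfg$nClasses ||
        length(cfg$classCaseProbs) != cfg$nClasses)
        stop("classWeights and classCaseProbs must have length nClasses")
    if (any(cfg$classCaseProbs < 0 | cfg$classCaseProbs > 1))
        stop("classCaseProbs must lie in [0, 1]")
    if (cfg$precision <= 0)
        stop("precision must be positive")
    if (!is.null(classPatterns) &&
        !identical(dim(classPatterns), c(cfg$nInformative, cfg$nClasses)))
        stop("classPatterns must be nInformative x nClasses")
    class(cfg) <- "SyntheticConfig"
    cfg
}

#' Generate a synthetic case/control cohort
#'
#' See [syntheticConfig()] for the generative model. Identical configuration
#' (including `seed`) reproduces identical output.
#'
#' @param cfg a `SyntheticConfig` from [syntheticConfig()].
#' @return list with `probes` ([ProbeMatrix-class] with the sample sheet as
#'   `colData`), `annotation` (island GRanges), `samples` (sample-sheet
#'   data.frame), `truth` (list: `classLabel`, `informativeIslandIds`,
#'   `classMeans` with islands x classes true mean betas).
#' @export
simulateCohort <- function(cfg) {
    stopifnot(inherits(cfg, "SyntheticConfig"))
    set.seed(cfg$seed)
    n <- cfg$nCases + cfg$nControls
    K <- cfg$nClasses

    # latent classes and case status
    cls <- sample.int(K, n, replace = TRUE, prob = cfg$classWeights)
    case <- stats::rbinom(n, 1L, cfg$classCaseProbs[cls])

    # island annotation: 1kb islands on autosomes, probes inside
    isl <- seq_len(cfg$nIslands)
    chrom <- paste0("chr", (isl - 1L) %% 22L + 1L)
    startPos <- 10000L + 5000L * isl
    ann <- GRanges(chrom, IRanges(start = startPos + 1L, width = 1000L))
    names(ann) <- sprintf("%s:%d-%d", chrom, startPos, startPos + 1000L)

    # class-conditional island means
    baseMean <- stats::runif(cfg$nIslands, 0.15, 0.85)
    classMeans <- matrix(baseMean, cfg$nIslands, K)
    infIdx <- integer(0)
    if (cfg$nInformative > 0L) {
        infIdx <- seq_len(cfg$nInformative)
        pat <- cfg$classPatterns
        if (is.null(pat)) {
            block <- cfg$classCaseProbs >= 0.8
            if (!any(block) || all(block))
                block <- seq_len(K) <= K %/% 2
            pat <- matrix(as.numeric(block), cfg$nInformative, K,
                          byrow = TRUE)
        }
        # keep both shifted and unshifted means well inside (0, 1)
        lo <- pmin(0, cfg$effectDelta); hi <- pmax(0, cfg$effectDelta)
        if (any(hi - lo >= 0.9))
            stop("infeasible config: |effectDelta| too large for means in (0, 1)")
        baseMean[infIdx] <- stats::runif(cfg$nInformative,
                                         0.05 - lo, 0.95 - hi)
        classMeans[infIdx, ] <- baseMean[infIdx] + cfg$effectDelta * pat
        classMeans <- matrix(pmin(pmax(classMeans, 0.02), 0.98),
                             cfg$nIslands, K)
    }

    # island-level values ~ beta(mean * conc, (1 - mean) * conc)
    mu <- classMeans[, cls, drop = FALSE]               # islands x samples
    islandBeta <- matrix(stats::rbeta(length(mu), mu * cfg$precision,
                                      (1 - mu) * cfg$precision),
                         cfg$nIslands, n)

    # probe values: island value + clipped gaussian scatter
    P <- cfg$nProbesPerIsland
    probeBeta <- islandBeta[rep(seq_len(cfg$nIslands), each = P), ,
                            drop = FALSE] +
        matrix(stats::rnorm(cfg$nIslands * P * n, 0, cfg$probeSd),
               cfg$nIslands * P, n)
    probeBeta <- pmin(pmax(probeBeta, 0), 1)

    # batch: round-robin, additive M-scale shift centered across batches
    batch <- rep_len(seq_len(cfg$batchLevels), n)
    shift <- cfg$batchShift * (batch - (cfg$batchLevels + 1) / 2)
    probeBeta <- .expit2(sweep(.logit2(.clampUnit(probeBeta)), 2L, shift, `+`))
    probeBeta <- pmin(pmax(probeBeta, 0), 1)

    sampleIds <- sprintf("S%03d", seq_len(n))
    colnames(probeBeta) <- sampleIds
    probeIds <- sprintf("cg%06d", seq_len(nrow(probeBeta)))
    rownames(probeBeta) <- probeIds
    probeChrom <- rep(chrom, each = P)
    probePos <- rep(startPos, each = P) + 100L * (seq_len(P) - 1L) +
        rep(rep(50L, cfg$nIslands), each = P)

    age <- stats::rnorm(n, 60, 10) + cfg$ageCaseShift * case
    sex <- stats::rbinom(n, 1L, 0.7)
    smoker <- stats::rbinom(n, 1L, 0.7)
    packYears <- round(smoker * stats::rgamma(n, shape = 2, scale = 12), 1)
    alcohol <- sample(c(0, 1, 3.5, 7, 14, 21), n, replace = TRUE,
                      prob = c(0.15, 0.2, 0.25, 0.2, 0.12, 0.08))
    ss <- data.frame(sample_id = sampleIds, case = case,
                     age = round(age, 1), sex = sex,
                     pack_years = packYears, alcohol = alcohol,
                     batch = paste0("B", batch),
                     stringsAsFactors = FALSE)

    pm <- ProbeMatrix(probeBeta, chrom = probeChrom, pos = probePos,
                      snpFlag = rep(FALSE, nrow(probeBeta)),
                      sampleData = ss)
    truth <- list(classLabel = cls,
                  informativeIslandIds = names(ann)[infIdx],
                  classMeans = classMeans)
    list(probes = pm, annotation = ann, samples = ss, truth = truth)
}

#' Generate paired tumor/normal island matrices
#'
#' Normal-tissue island betas are drawn from beta distributions with
#' island-specific means and concentration `precision`; the paired tumor
#' value is drawn around the normal value shifted by the island's delta
#' (clipped into (0, 1)), with the same concentration. Pairing is by column
#' position, returned explicitly.
#'
#' @param nPairs number of tumor/normal pairs (>= 2).
#' @param islandDeltas per-island tumor-minus-normal mean shift.
#' @param precision beta concentration; default 100.
#' @param seed integer seed.
#' @return list with `tumor` and `normal` ([IslandMatrix-class], same island
#'   and pair order) and `pairing` (data.frame of tumor/normal sample ids).
#' @export
simulatePairs <- function(nPairs, islandDeltas, precision = 100, seed = 1L) {
    if (nPairs < 2L) stop("nPairs must be >= 2")
    if (precision <= 0) stop("precision must be positive")
    set.seed(as.integer(seed))
    p <- length(islandDeltas)
    mu <- stats::runif(p, 0.2, 0.8)
    bad <- mu + islandDeltas >= 0.98 | mu + islandDeltas <= 0.02
    mu[bad] <- 0.5 - islandDeltas[bad] / 2
    if (any(mu + islandDeltas >= 1 | mu + islandDeltas <= 0 |
            mu <= 0 | mu >= 1))
        stop("infeasible islandDeltas: shifted mean outside (0, 1)")
    normal <- matrix(stats::rbeta(p * nPairs, mu * precision,
                                  (1 - mu) * precision), p, nPairs)
    tumorMean <- pmin(pmax(normal + islandDeltas, 0.02), 0.98)
    tumor <- matrix(stats::rbeta(p * nPairs, tumorMean * precision,
                                 (1 - tumorMean) * precision), p, nPairs)
    ids <- sprintf("isl%03d", seq_len(p))
    tn <- sprintf("T%03d", seq_len(nPairs))
    nn <- sprintf("N%03d", seq_len(nPairs))
    dimnames(normal) <- list(ids, nn)
    dimnames(tumor) <- list(ids, tn)
    list(tumor = IslandMatrix(tumor), normal = IslandMatrix(normal),
         pairing = data.frame(tumor = tn, normal = nn,
                              stringsAsFactors = FALSE))
}
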