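#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowData colData colData<-
NULL

#' Probe-level methylation matrix
#'
#' `ProbeMatrix` holds Illumina 450K-style probe-level beta values (one row
#' per probe, one column per sample) together with probe genomic positions,
#' SNP flags, and optional per-probe/per-sample detection p-values. It extends
#' [SummarizedExperiment::RangedSummarizedExperiment]: probe coordinates live
#' in `rowRanges()` (width-1 ranges; the original 0-based position is kept in
#' `mcols()$pos0`), sample annotation in `colData()`.
#'
#' Validity requires all beta values finite and in \[0, 1\], unique probe
#' identifiers, and a `detectionP` assay (when present) with values in
#' \[0, 1\].
#'
#' @seealso [ProbeMatrix()] for construction, [filterProbes()],
#'   [aggregateIslands()]
#' @aliases ProbeMatrix-class
#' @exportClass ProbeMatrix
setClass("ProbeMatrix", contains = "RangedSummarizedExperiment")

setValidity("ProbeMatrix", function(object) {
    msg <- character()
    if (!"beta" %in% names(assays(object)))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        if (!all(is.finite(b)))
            msg <- c(msg, "beta values must be finite")
        else if (any(b < 0 | b > 1))
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    ids <- rownames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "probe ids (rownames) must be present and unique")
    if ("detectionP" %in% names(assays(object))) {
        dp <- assay(object, "detectionP")
        if (any(dp < 0 | dp > 1, na.rm = TRUE))
            msg <- c(msg, "detection p-values must lie in [0, 1]")
    }
    if (is.null(mcols(rowRanges(object))$snpFlag))
        msg <- c(msg, "rowRanges must carry an 'snpFlag' column")
    if (length(msg)) msg else TRUE
})

#' Island-level methylation matrix
#'
#' `IslandMatrix` holds CpG-island mean beta values (islands x samples) with
#' the island intervals as `rowRanges()` and the number of contributing
#' probes in `rowData()$nProbes`. Produced by [aggregateIslands()].
#'
#' @aliases IslandMatrix-class
#' @exportClass IslandMatrix
setClass("IslandMatrix", contains = "RangedSummarizedExperiment")

setValidity("IslandMatrix", function(object) {
    msg <- character()
    if (!"avgBeta" %in% names(assays(object)))
        msg <- c(msg, "assay 'avgBeta' is required")
    else {
        b <- assay(object, "avgBeta")
        if (!all(is.finite(b)) || any(b < 0 | b > 1))
            msg <- c(msg, "avgBeta values must be finite and in [0, 1]")
    }
    ids <- rownames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "island ids (rownames) must be present and unique")
    if (is.null(rowData(object)$nProbes))
        msg <- c(msg, "rowData must carry 'nProbes'")
    if (length(msg)) msg else TRUE
})

#' Fitted recursively partitioned beta-mixture model
#'
#' The fitted RPMM tree. Each node is a list with elements `name` (a string
#' over the alphabet \{r, L, R\} with prefix "r"; children append "L"/"R"),
#' `weight` (expected fraction of samples reaching the node), `a`/`b`
#' (per-feature beta shape vectors), and `children` (NULL for leaves, else a
#' list of the left and right child). Terminal classes are the leaves in
#' left-before-right traversal order; their weights sum to one.
#'
#' @slot root list; the recursive node structure described above.
#' @slot featureIds character; the ordered feature (island) ids the model was
#'   fit on.
#' @slot terminalClasses character; leaf names in left-to-right order.
#' @slot trainPosteriors matrix; training-sample posteriors over terminal
#'   classes (rows sum to 1), possibly 0-row after deserialization.
#' @aliases RPMMModel-class
#' @exportClass RPMMModel
setClass("RPMMModel", representation(
    root = "list",
    featureIds = "character",
    terminalClasses = "character",
    trainPosteriors = "matrix"
))

.collectLeaves <- function(node) {
    if (is.null(node$children))
        return(list(node))
    c(.collectLeaves(node$children[[1L]]), .collectLeaves(node$children[[2L]]))
}

setValidity("RPMMModel", function(object) {
    msg <- character()
    if (!length(object@featureIds))
        msg <- c(msg, "featureIds must be non-empty")
    if (!identical(object@root$name, "r"))
        msg <- c(msg, "root node must be named 'r'")
    leaves <- .collectLeaves(object@root)
    nms <- vapply(leaves, `[[`, character(1), "name")
    if (!identical(nms, object@terminalClasses))
        msg <- c(msg, "terminalClasses must equal the left-to-right leaf traversal")
    w <- vapply(leaves, `[[`, numeric(1), "weight")
    if (abs(sum(w) - 1) > 1e-8)
        msg <- c(msg, "terminal class weights must sum to 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RPMMModel", function(object) {
    cat("RPMMModel on", length(object@featureIds), "features;",
        length(object@terminalClasses), "terminal classes\n")
    leaves <- .collectLeaves(object@root)
    for (lf in leaves)
        cat(sprintf("  %-8s weight %.3f\n", lf$name, lf$weight))
})

#' Portable island methylation classifier
#'
#' Bundles the selected top-M islands (in rank order) with the RPMM fitted on
#' them and, when produced by [nestedCVSelectM()], the cross-validation trace
#' over candidate M values.
#'
#' @slot mSelected integer; number of islands (M).
#' @slot islandIds character; the top-M island ids in rank order.
#' @slot model the fitted [RPMMModel-class].
#' @slot cvTrace data.frame with columns `m` and `objective` (may be 0-row).
#' @aliases ClassifierSpec-class
#' @exportClass ClassifierSpec
setClass("ClassifierSpec", representation(
    mSelected = "integer",
    islandIds = "character",
    model = "RPMMModel",
    cvTrace = "data.frame"
))

setValidity("ClassifierSpec", function(object) {
    msg <- character()
    if (length(object@islandIds) != object@mSelected)
        msg <- c(msg, "length(islandIds) must equal mSelected")
    if (!identical(object@islandIds, object@model@featureIds))
        msg <- c(msg, "model featureIds must equal islandIds")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ClassifierSpec", function(object) {
    cat("ClassifierSpec: M =", object@mSelected, "islands,",
        length(object@model@terminalClasses), "methylation classes\n")
    cat("  islands:", paste(utils::head(object@islandIds, 5), collapse = ", "),
        if (object@mSelected > 5) "..." else "", "\n")
})
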