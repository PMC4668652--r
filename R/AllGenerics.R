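#' @rdname betaValues
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname avgBeta
#' @export
setGeneric("avgBeta", function(x) standardGeneric("avgBeta"))

#' @rdname nProbes
#' @export
setGeneric("nProbes", function(x) standardGeneric("nProbes"))

#' @rdname islandIds
#' @export
setGeneric("islandIds", function(x) standardGeneric("islandIds"))

#' @rdname terminalClasses
#' @export
setGeneric("terminalClasses", function(x) standardGeneric("terminalClasses"))

#' Probe-level beta values
#'
#' @param x a [ProbeMatrix-class]
#' @return numeric matrix, probes x samples, values in \[0, 1\].
#' @export
setMethod("betaValues", "ProbeMatrix", function(x) assay(x, "beta"))

#' Island-level mean beta values
#'
#' @param x an [IslandMatrix-class]
#' @return numeric matrix, islands x samples.
#' @export
setMethod("avgBeta", "IslandMatrix", function(x) assay(x, "avgBeta"))

#' Per-island contributing probe counts
#'
#' @param x an [IslandMatrix-class]
#' @return integer vector named by island id.
#' @export
setMethod("nProbes", "IslandMatrix", function(x) {
    stats::setNames(rowData(x)$nProbes, rownames(x))
})

#' Island identifiers
#'
#' @param x an [IslandMatrix-class]
#' @return character vector of island ids.
#' @export
setMethod("islandIds", "IslandMatrix", function(x) rownames(x))

#' Terminal methylation class names
#'
#' Leaf names of the fitted RPMM dendrogram, left branch before right, e.g.
#' `"rL"`, `"rRL"`, `"rRRR"`.
#'
#' @param x an [RPMMModel-class] or [ClassifierSpec-class]
#' @return character vector of class names.
#' @export
setMethod("terminalClasses", "RPMMModel", function(x) x@terminalClasses)

#' @rdname terminalClasses
#' @export
setMethod("terminalClasses", "ClassifierSpec", function(x) x@model@terminalClasses)
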