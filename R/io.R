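#' Construct a ProbeMatrix
#'
#' @param beta numeric matrix of beta values in \[0, 1\], probes x samples;
#'   rownames are probe ids, colnames sample ids.
#' @param chrom character vector of probe chromosomes.
#' @param pos integer vector of probe positions (0-based, matching the BED
#'   convention used for island intervals).
#' @param snpFlag logical vector; TRUE for probes whose sequence contains a
#'   SNP.
#' @param detectionP optional numeric matrix of detection p-values, same
#'   dimensions as `beta`.
#' @param sampleData optional data.frame of per-sample annotation (one row
#'   per column of `beta`).
#' @return a [ProbeMatrix-class]
#' @export
ProbeMatrix <- function(beta, chrom, pos, snpFlag = rep(FALSE, nrow(beta)),
                        detectionP = NULL, sampleData = NULL) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)))
        stop("'beta' must have probe ids as rownames")
    if (length(chrom) != nrow(beta) || length(pos) != nrow(beta) ||
        length(snpFlag) != nrow(beta))
        stop("probe metadata length must match nrow(beta)")
    rr <- GRanges(chrom, IRanges(start = as.integer(pos) + 1L, width = 1L))
    names(rr) <- rownames(beta)
    mcols(rr)$pos0 <- as.integer(pos)
    mcols(rr)$snpFlag <- as.logical(snpFlag)
    assays <- list(beta = beta)
    if (!is.null(detectionP)) {
        detectionP <- as.matrix(detectionP)
        if (!identical(dim(detectionP), dim(beta)))
            stop("'detectionP' must have the same dimensions as 'beta'")
        dimnames(detectionP) <- dimnames(beta)
        assays$detectionP <- detectionP
    }
    cd <- if (is.null(sampleData)) {
        DataFrame(row.names = colnames(beta))
    } else {
        DataFrame(sampleData, row.names = colnames(beta))
    }
    se <- SummarizedExperiment(assays = assays, rowRanges = rr, colData = cd)
    new("ProbeMatrix", se)
}

#' Construct an IslandMatrix
#'
#' Usually produced by [aggregateIslands()]; exported for the synthetic
#' generator and tests.
#'
#' @param avgBeta numeric matrix in \[0, 1\], islands x samples, rownames =
#'   island ids.
#' @param ranges [GenomicRanges::GRanges] of island intervals (same order as
#'   rows); optional — placeholder single-base ranges are used if omitted.
#' @param nProbes integer vector of per-island contributing probe counts.
#' @return an [IslandMatrix-class]
#' @export
IslandMatrix <- function(avgBeta, ranges = NULL,
                         nProbes = rep(NA_integer_, nrow(avgBeta))) {
    avgBeta <- as.matrix(avgBeta)
    if (is.null(rownames(avgBeta)))
        stop("'avgBeta' must have island ids as rownames")
    if (is.null(ranges))
        ranges <- GRanges("chrU", IRanges(seq_len(nrow(avgBeta)), width = 1L))
    names(ranges) <- rownames(avgBeta)
    mcols(ranges)$nProbes <- as.integer(nProbes)
    se <- SummarizedExperiment(assays = list(avgBeta = avgBeta),
                               rowRanges = ranges)
    new("IslandMatrix", se)
}

#' Beta value from two-channel intensities
#'
#' Computes the methylation proportion from methylated (Cy5) and unmethylated
#' (Cy3) channel fluorescence as
#' `max(cy5, 0) / (|cy3| + |cy5| + 100)`. The offset of 100 regularizes
#' low-intensity probes; negative methylated signal (possible after
#' background correction) is clipped to zero, so the result lies in \[0, 1).
#'
#' @param cy5 numeric; methylated-channel intensity (may be negative).
#' @param cy3 numeric; unmethylated-channel intensity.
#' @return numeric vector of beta values in \[0, 1).
#' @examples
#' betaFromIntensities(900, 0)    # 0.9
#' betaFromIntensities(-50, 150)  # 0
#' @export
betaFromIntensities <- function(cy5, cy3) {
    if (!all(is.finite(cy5)) || !all(is.finite(cy3)))
        stop("intensities must be finite")
    pmax(cy5, 0) / (abs(cy3) + abs(cy5) + 100)
}

#' Filter probes by detection quality and SNP content
#'
#' Removes SNP-flagged probes and probes whose detection p-value exceeds the
#' threshold in any sample (an array-wide probe mask: a probe failing
#' detection in one sample is dropped for all). Survivor order is preserved.
#'
#' @param pm a [ProbeMatrix-class]
#' @param detectionThreshold detection p-value cutoff in (0, 1\]; default 0.01.
#' @param dropSNP drop SNP-flagged probes; default TRUE.
#' @return the filtered [ProbeMatrix-class]; a warning (not an error) is
#'   raised if no probe survives.
#' @export
filterProbes <- function(pm, detectionThreshold = 0.01, dropSNP = TRUE) {
    stopifnot(is(pm, "ProbeMatrix"))
    if (!is.numeric(detectionThreshold) || detectionThreshold <= 0 ||
        detectionThreshold > 1)
        stop("'detectionThreshold' must be in (0, 1]")
    keep <- rep(TRUE, nrow(pm))
    if (dropSNP)
        keep <- keep & !mcols(rowRanges(pm))$snpFlag
    if ("detectionP" %in% names(assays(pm))) {
        failAny <- apply(assay(pm, "detectionP") > detectionThreshold, 1L, any)
        keep <- keep & !failAny
    }
    out <- pm[keep, ]
    if (nrow(out) == 0L)
        warning("no probes survive filtering")
    out
}

.SEX_CHROMS <- c("chrX", "chrY", "chrM", "X", "Y", "MT", "M")

#' Average probes into CpG-island-level beta values
#'
#' For each island interval, the island-level methylation of a sample is the
#' arithmetic mean of the beta values of all probes whose position falls
#' inside the interval (BED convention: 0-based half-open, so a probe at
#' position p belongs to \[start, end) iff start <= p < end). Islands covered
#' by fewer than `minProbes` probes after filtering are dropped, as are
#' islands on sex chromosomes when `autosomesOnly`.
#'
#' @param pm a (filtered) [ProbeMatrix-class]
#' @param ann island annotation: a named [GenomicRanges::GRanges] as returned
#'   by [readIslandAnnotation()].
#' @param minProbes minimum probes per retained island; default 3.
#' @param autosomesOnly drop islands on chrX/chrY/chrM; default TRUE.
#' @return an [IslandMatrix-class]
#' @export
aggregateIslands <- function(pm, ann, minProbes = 3L, autosomesOnly = TRUE) {
    stopifnot(is(pm, "ProbeMatrix"), is(ann, "GRanges"))
    if (nrow(pm) == 0L || length(ann) == 0L)
        stop("probe matrix and annotation must be non-empty")
    if (is.null(names(ann)) || anyDuplicated(names(ann)))
        stop("island annotation must carry unique island ids as names")
    keepIsl <- rep(TRUE, length(ann))
    if (autosomesOnly)
        keepIsl <- !(as.character(seqnames(ann)) %in% .SEX_CHROMS)
    ann <- ann[keepIsl]
    hits <- findOverlaps(rowRanges(pm), ann, ignore.strand = TRUE)
    if (length(hits) == 0L)
        stop("no island is covered by any probe: empty feature space")
    grp <- factor(S4Vectors::subjectHits(hits), levels = seq_along(ann))
    counts <- as.integer(table(grp))
    b <- betaValues(pm)[S4Vectors::queryHits(hits), , drop = FALSE]
    sums <- rowsum(b, grp)
    keep <- counts >= minProbes
    if (!any(keep))
        stop("no island retains at least ", minProbes,
             " probes: empty feature space")
    avg <- sums[keep, , drop = FALSE] / counts[keep]
    rownames(avg) <- names(ann)[keep]
    IslandMatrix(avg, ranges = ann[keep], nProbes = counts[keep])
}

#' Logit (M-value) transform of beta values
#'
#' `M = log2(b / (1 - b))` with `b` clamped to
#' \[`epsilon`, 1 - `epsilon`\] so boundary values stay finite. M-values are
#' the variance-stabilized scale used for linear modelling of methylation.
#'
#' @param beta numeric vector or matrix of beta values in \[0, 1\].
#' @param epsilon clamp bound in (0, 0.5); default 1e-6.
#' @return numeric of the same shape.
#' @examples
#' mValues(c(0.5, 0.8))  # 0, 2
#' @export
mValues <- function(beta, epsilon = 1e-6) {
    if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5)
        stop("'epsilon' must be in (0, 0.5)")
    .logit2(.clampUnit(beta, epsilon))
}

#' Read a CpG-island annotation (BED3+1)
#'
#' @param path BED file with columns chrom, start, end, island_id (0-based
#'   half-open intervals).
#' @return a named [GenomicRanges::GRanges]
#' @export
readIslandAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- mcols(gr)$name
    if (is.null(ids) || anyNA(ids))
        stop("island annotation ", path, " must have an id (name) column")
    if (anyDuplicated(ids))
        stop("duplicated island id in ", path, ": ",
             ids[anyDuplicated(ids)])
    names(gr) <- ids
    gr
}

.REQUIRED_SHEET_COLS <- c("sample_id", "case", "age", "sex", "pack_years",
                          "alcohol", "batch")

#' Read and validate a sample sheet (CSV)
#'
#' Expected header: `sample_id,case,age,sex,pack_years,alcohol,batch` with an
#' optional `split` column (values "train"/"test") and any further columns
#' kept as-is. `case` must be 0/1 and `pack_years` non-negative.
#'
#' @param path CSV file path.
#' @return data.frame, one row per sample.
#' @export
readSampleSheet <- function(path) {
    ss <- utils::read.csv(path, stringsAsFactors = FALSE)
    validateSampleSheet(ss, context = path)
}

#' Validate a sample-sheet data.frame
#'
#' @param ss data.frame to validate.
#' @param context label used in error messages.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validateSampleSheet <- function(ss, context = "sample sheet") {
    missingCols <- setdiff(.REQUIRED_SHEET_COLS, names(ss))
    if (length(missingCols))
        stop(context, ": missing required column(s) ",
             paste(missingCols, collapse = ", "))
    if (anyDuplicated(ss$sample_id))
        stop(context, ": duplicated sample_id ",
             ss$sample_id[anyDuplicated(ss$sample_id)])
    if (!all(ss$case %in% c(0L, 1L)))
        stop(context, ": 'case' must be 0/1")
    if (any(ss$pack_years < 0, na.rm = TRUE))
        stop(context, ": 'pack_years' must be non-negative")
    if ("split" %in% names(ss) &&
        !all(ss$split %in% c("train", "test", NA)))
        stop(context, ": 'split' values must be 'train' or 'test'")
    ss
}

#' Read a probe-level methylation dataset
#'
#' Reads the three standard inputs and cross-validates them: a beta TSV
#' (first column `probe_id`, one column per sample), a companion probe
#' metadata TSV (`probe_id, chrom, pos, snp_flag`, positions 0-based), a
#' BED3+1 island annotation and a sample-sheet CSV. An optional long-format
#' detection p-value TSV (`probe_id, sample_id, detection_p`) is folded into
#' the `detectionP` assay. Matrix sample columns are re-ordered to the sample
#' sheet; any mismatch between matrix and sheet samples, duplicated ids, or
#' out-of-range beta is reported with the offending probe/sample named.
#'
#' @param probePath beta TSV path.
#' @param annotationPath BED3+1 island annotation path.
#' @param samplePath sample-sheet CSV path.
#' @param probeMetaPath probe metadata TSV; default
#'   `<probePath without extension>_meta.tsv`.
#' @param detectionPath optional long-format detection-p TSV.
#' @return list with elements `probes` ([ProbeMatrix-class], sample sheet in
#'   `colData`), `annotation` (GRanges), `samples` (data.frame).
#' @export
readMethylDataset <- function(probePath, annotationPath, samplePath,
                              probeMetaPath = NULL, detectionPath = NULL) {
    if (is.null(probeMetaPath))
        probeMetaPath <- paste0(tools::file_path_sans_ext(probePath),
                                "_meta.tsv")
    for (p in c(probePath, annotationPath, samplePath, probeMetaPath))
        if (!file.exists(p)) stop("input file not found: ", p)

    betaDf <- utils::read.delim(probePath, check.names = FALSE,
                                stringsAsFactors = FALSE)
    if (names(betaDf)[1L] != "probe_id")
        stop(probePath, ": first column must be 'probe_id'")
    if (anyDuplicated(betaDf$probe_id))
        stop(probePath, ": duplicated probe_id ",
             betaDf$probe_id[anyDuplicated(betaDf$probe_id)])
    beta <- as.matrix(betaDf[, -1L, drop = FALSE])
    rownames(beta) <- betaDf$probe_id
    bad <- which(!is.finite(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
    if (nrow(bad))
        stop(probePath, ": beta value out of [0, 1] for probe ",
             rownames(beta)[bad[1L, 1L]], ", sample ",
             colnames(beta)[bad[1L, 2L]])

    meta <- utils::read.delim(probeMetaPath, stringsAsFactors = FALSE)
    need <- c("probe_id", "chrom", "pos", "snp_flag")
    if (!all(need %in% names(meta)))
        stop(probeMetaPath, ": required columns are ",
             paste(need, collapse = ", "))
    if (!setequal(meta$probe_id, rownames(beta)))
        stop(probeMetaPath, ": probe ids do not match the beta matrix")
    meta <- meta[match(rownames(beta), meta$probe_id), ]

    ss <- readSampleSheet(samplePath)
    extraMat <- setdiff(colnames(beta), ss$sample_id)
    if (length(extraMat))
        stop(probePath, ": sample ", extraMat[1L],
             " is absent from the sample sheet")
    extraSheet <- setdiff(ss$sample_id, colnames(beta))
    if (length(extraSheet))
        stop(samplePath, ": sample ", extraSheet[1L],
             " is absent from the beta matrix")
    beta <- beta[, ss$sample_id, drop = FALSE]

    detP <- NULL
    if (!is.null(detectionPath)) {
        dl <- utils::read.delim(detectionPath, stringsAsFactors = FALSE)
        if (!all(c("probe_id", "sample_id", "detection_p") %in% names(dl)))
            stop(detectionPath,
                 ": required columns are probe_id, sample_id, detection_p")
        detP <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
        i <- match(dl$probe_id, rownames(beta))
        j <- match(dl$sample_id, colnames(beta))
        if (anyNA(i) || anyNA(j))
            stop(detectionPath, ": unknown probe or sample id")
        detP[cbind(i, j)] <- dl$detection_p
    }

    pm <- ProbeMatrix(beta, chrom = meta$chrom, pos = meta$pos,
                      snpFlag = as.logical(meta$snp_flag),
                      detectionP = detP, sampleData = ss)
    ann <- readIslandAnnotation(annotationPath)
    list(probes = pm, annotation = ann, samples = ss)
}

#' Write a probe-level methylation dataset
#'
#' Inverse of [readMethylDataset()]: writes the beta TSV, probe metadata TSV,
#' BED3+1 annotation and sample-sheet CSV in the package's file dialects.
#' Numeric values are written with 17 significant digits so that a
#' read-write-read cycle reproduces the objects exactly.
#'
#' @param pm a [ProbeMatrix-class]
#' @param ann island annotation GRanges.
#' @param ss sample-sheet data.frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeMethylDataset <- function(pm, ann, ss, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(probes = file.path(dir, "beta.tsv"),
               meta = file.path(dir, "beta_meta.tsv"),
               annotation = file.path(dir, "islands.bed"),
               samples = file.path(dir, "samples.csv"))
    b <- betaValues(pm)
    bOut <- data.frame(probe_id = rownames(b),
                       apply(b, 2L, sprintf, fmt = "%.17g"),
                       check.names = FALSE)
    utils::write.table(bOut, paths["probes"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rr <- rowRanges(pm)
    metaOut <- data.frame(probe_id = names(rr),
                          chrom = as.character(seqnames(rr)),
                          pos = mcols(rr)$pos0,
                          snp_flag = mcols(rr)$snpFlag)
    utils::write.table(metaOut, paths["meta"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    bedOut <- data.frame(chrom = as.character(seqnames(ann)),
                         start = start(ann) - 1L, end = end(ann),
                         id = names(ann))
    utils::write.table(bedOut, paths["annotation"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.csv(ss, paths["samples"], row.names = FALSE, quote = FALSE)
    invisible(paths)
}
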