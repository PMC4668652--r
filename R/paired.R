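# Paired tumor-vs-normal differential methylation of classifier islands.

# Two-sided Wilcoxon signed-rank p-value for paired differences d.
# Zeros are dropped (Wilcoxon's convention). Exact null distribution via
# psignrank for <= `exactMax` non-zero untied pairs; otherwise the normal
# approximation with continuity correction and the tie correction of the
# rank variance.
.signedRankP <- function(d, exactMax = 25L) {
    dnz <- d[d != 0]
    n <- length(dnz)
    if (n == 0L) return(1)
    r <- rank(abs(dnz))
    W <- sum(r[dnz > 0])
    ties <- anyDuplicated(abs(dnz)) > 0L
    if (n <= exactMax && !ties) {
        pUp <- 1 - stats::psignrank(W - 1, n)
        pLo <- stats::psignrank(W, n)
        return(min(1, 2 * min(pUp, pLo)))
    }
    mu <- n * (n + 1) / 4
    tieTab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(tieTab^3 - tieTab) / 48
    if (sigma2 <= 0) return(1)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
}

#' Paired tumor/normal differential methylation per island
#'
#' For each island, computes the per-pair differences tumor minus normal, a
#' two-sided Wilcoxon signed-rank p-value (zeros dropped; exact null for at
#' most 25 untied non-zero pairs, normal approximation with continuity and
#' tie correction otherwise), the median and range of the differences over
#' all pairs (zeros included), and Benjamini-Hochberg q-values across
#' islands. Positive median differences denote relative hypermethylation of
#' tumor tissue.
#'
#' @param tumor,normal [IslandMatrix-class] objects (or plain matrices) with
#'   identical island sets.
#' @param pairing optional data.frame with columns `tumor` and `normal`
#'   giving the sample-id bijection; default pairs columns by position.
#' @return data.frame with columns `island_id`, `median_diff`, `diff_min`,
#'   `diff_max`, `p_value`, `q_value`.
#' @export
pairedIslandTest <- function(tumor, normal, pairing = NULL) {
    tm <- if (is(tumor, "IslandMatrix")) avgBeta(tumor) else as.matrix(tumor)
    nm <- if (is(normal, "IslandMatrix")) avgBeta(normal) else
        as.matrix(normal)
    if (!identical(rownames(tm), rownames(nm)))
        stop("tumor and normal must cover the same islands in the same order")
    if (is.null(pairing)) {
        if (ncol(tm) != ncol(nm))
            stop("pairing is not a bijection: unequal sample counts")
        pairing <- data.frame(tumor = colnames(tm), normal = colnames(nm),
                              stringsAsFactors = FALSE)
    }
    if (anyDuplicated(pairing$tumor) || anyDuplicated(pairing$normal) ||
        !setequal(pairing$tumor, colnames(tm)) ||
        !setequal(pairing$normal, colnames(nm)))
        stop("pairing is not a bijection between tumor and normal samples")
    if (nrow(pairing) < 6L)
        warning("fewer than 6 pairs: signed-rank p-values are uninformative")
    d <- tm[, pairing$tumor, drop = FALSE] -
        nm[, pairing$normal, drop = FALSE]
    p <- apply(d, 1L, .signedRankP)
    out <- data.frame(island_id = rownames(tm),
                      median_diff = apply(d, 1L, stats::median),
                      diff_min = apply(d, 1L, min),
                      diff_max = apply(d, 1L, max),
                      p_value = p,
                      stringsAsFactors = FALSE)
    out$q_value <- bhAdjust(out$p_value)
    rownames(out) <- NULL
    out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): on the sorted scale
#' `q_(i) = min over j >= i of (m / j) p_(j)`, capped at 1 and mapped back
#' to the input order.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pValues) {
    if (any(!is.finite(pValues)) || any(pValues < 0 | pValues > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pValues, method = "BH")
}

#' Count islands significant at an FDR threshold
#'
#' @param results data.frame from [pairedIslandTest()] (needs a `q_value`
#'   column).
#' @param qThreshold FDR threshold; default 0.05.
#' @return integer count of islands with `q_value < qThreshold`.
#' @export
countSignificant <- function(results, qThreshold = 0.05) {
    if (!nrow(results)) stop("empty results")
    sum(results$q_value < qThreshold)
}
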