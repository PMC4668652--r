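# Recursively partitioned product-beta mixture model.
#
# The class-conditional likelihood is a product of independent beta densities
# per feature; values are clamped 1e-6 from the [0,1] boundaries before any
# likelihood evaluation. Recursion is fuzzy: children inherit the parent's
# sample weights multiplied by the two-component membership posteriors.

.BETA_CLAMP <- 1e-6

# Method-of-moments beta shapes from a mean and variance
# (uniform moments m = 1/2, v = 1/12 give exactly a = b = 1).
.momBeta <- function(m, v) {
    conc <- m * (1 - m) / v - 1
    c(a = m * conc, b = (1 - m) * conc)
}

#' Weighted maximum-likelihood beta fit
#'
#' Fits beta shape parameters to weighted observations in \[0, 1\]. Starting
#' values come from the weighted method of moments — with mean `m` and
#' variance `v`, `a = m(m(1-m)/v - 1)`, `b = (1-m)(m(1-m)/v - 1)` — and are
#' refined by damped Newton iterations on the weighted log-likelihood
#' (step-halving guarantees the refined log-likelihood is never below the
#' moment fit's). Observations are clamped to \[1e-6, 1-1e-6\]. Data more
#' dispersed than any beta distribution allows (`v >= m(1-m)`) fall back to a
#' clipped moment fit with unit concentration `a + b = 2`.
#'
#' @param x numeric values in \[0, 1\].
#' @param w non-negative weights (default equal); must not sum to zero.
#' @return list with `a`, `b`, `loglik` (weighted), `converged`, `method`
#'   ("newton" or "moments").
#' @export
weightedBetaFit <- function(x, w = NULL) {
    if (is.null(w)) w <- rep(1, length(x))
    if (length(w) != length(x) || any(w < 0) || sum(w) <= 0)
        stop("weights must be non-negative with positive sum")
    pos <- w > 0
    if (length(unique(x[pos])) < 2L)
        stop("need at least 2 distinct values with positive weight")
    xc <- .clampUnit(x, .BETA_CLAMP)
    W <- sum(w)
    # moments on the raw values: two-point mass at 0/1 must register as
    # overdispersed (v = m(1-m)), which clamping would hide
    m <- sum(w * x) / W
    v <- sum(w * (x - m)^2) / W
    slx <- sum(w * log(xc))
    sl1x <- sum(w * log1p(-xc))
    ll <- function(a, b) (a - 1) * slx + (b - 1) * sl1x - W * lbeta(a, b)

    if (v <= 0 || v >= m * (1 - m)) {
        a <- max(2 * m, 1e-3); b <- max(2 * (1 - m), 1e-3)
        return(list(a = a, b = b, loglik = ll(a, b), converged = TRUE,
                    method = "moments"))
    }
    mom <- .momBeta(m, v)
    a <- min(max(mom[["a"]], 1e-3), 1e6)
    b <- min(max(mom[["b"]], 1e-3), 1e6)
    cur <- ll(a, b)
    converged <- FALSE
    for (it in seq_len(50L)) {
        ga <- slx - W * (digamma(a) - digamma(a + b))
        gb <- sl1x - W * (digamma(b) - digamma(a + b))
        tab <- W * trigamma(a + b)
        haa <- -W * trigamma(a) + tab
        hbb <- -W * trigamma(b) + tab
        det <- haa * hbb - tab * tab
        if (!is.finite(det) || abs(det) < 1e-300) break
        da <- -(hbb * ga - tab * gb) / det
        db <- -(-tab * ga + haa * gb) / det
        step <- 1
        improved <- FALSE
        for (h in seq_len(30L)) {
            a2 <- a + step * da; b2 <- b + step * db
            if (a2 > 0 && b2 > 0) {
                new <- ll(a2, b2)
                if (is.finite(new) && new >= cur) {
                    a <- a2; b <- b2
                    improved <- TRUE
                    if (new - cur < 1e-10 * (abs(cur) + 1)) {
                        cur <- new; converged <- TRUE
                    } else cur <- new
                    break
                }
            }
            step <- step / 2
        }
        if (!improved || converged) { converged <- TRUE; break }
    }
    list(a = a, b = b, loglik = cur, converged = converged, method = "newton")
}

#' Per-sample product-beta log-likelihood
#'
#' Sum over features of the beta log-density at the clamped value, one total
#' per sample (row).
#'
#' @param x numeric matrix, samples x features, values in \[0, 1\].
#' @param params list with numeric vectors `a` and `b`, one entry per
#'   feature.
#' @return numeric vector of per-sample log-likelihoods.
#' @export
betaLoglik <- function(x, params) {
    x <- as.matrix(x)
    if (length(params$a) != ncol(x) || length(params$b) != ncol(x))
        stop("parameter vectors must match the number of feature columns")
    xc <- .clampUnit(x, .BETA_CLAMP)
    n <- nrow(xc)
    am <- matrix(params$a, n, ncol(xc), byrow = TRUE)
    bm <- matrix(params$b, n, ncol(xc), byrow = TRUE)
    rowSums(stats::dbeta(xc, am, bm, log = TRUE))
}

# One-class weighted fit over all features; returns params and total
# weighted log-likelihood.
.fitNodeParams <- function(x, w) {
    p <- ncol(x)
    a <- numeric(p); b <- numeric(p); llTot <- 0
    for (j in seq_len(p)) {
        f <- weightedBetaFit(x[, j], w)
        a[j] <- f$a; b[j] <- f$b; llTot <- llTot + f$loglik
    }
    list(params = list(a = a, b = b), loglik = llTot)
}

# Weighted log-likelihood of one component/feature pair; used by the
# generalized-EM guard.
.wFeatureLL <- function(xj, wj, a, b) {
    xc <- .clampUnit(xj, .BETA_CLAMP)
    sum(wj * stats::dbeta(xc, a, b, log = TRUE))
}

#' Two-component product-beta EM
#'
#' Fits a two-component mixture of product-beta densities to weighted
#' samples. Initialization is deterministic: samples are soft-assigned by the
#' sign of their score on the first principal direction of the weighted,
#' centered logit-transformed data (the direction's sign is fixed by its
#' largest-magnitude loading, so the result does not depend on sample
#' order). Each M-step refines the per-feature beta parameters with
#' [weightedBetaFit()], keeping the previous parameters whenever the refit
#' would lower that component's weighted likelihood (a generalized EM step),
#' so the observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param x numeric matrix, samples x features, in \[0, 1\].
#' @param sampleWeights non-negative per-sample weights (default equal).
#' @param seed integer seed (used only to break degenerate initialization
#'   ties).
#' @param maxIter maximum EM iterations; default 1000.
#' @param tol relative log-likelihood convergence tolerance; default 1e-8.
#' @return list with `pi` (first-component mixture weight), `params` (list of
#'   two `a`/`b` parameter lists), `resp` (n x 2 membership posteriors),
#'   `loglik`, `loglikTrace`, `converged`, `degenerate`.
#' @export
emTwoClass <- function(x, sampleWeights = NULL, seed = 1L,
                       maxIter = 1000L, tol = 1e-8) {
    x <- as.matrix(x)
    n <- nrow(x)
    if (is.null(sampleWeights)) sampleWeights <- rep(1, n)
    w <- sampleWeights
    if (any(w < 0) || sum(w) <= 0)
        stop("sample weights must be non-negative with positive sum")

    z <- .logit2(.clampUnit(x, .BETA_CLAMP))
    wn <- w / sum(w)
    mu <- colSums(z * wn)
    zc <- sweep(z, 2L, mu)
    sv <- svd(sqrt(wn) * zc, nu = 0L, nv = 1L)
    v1 <- sv$v[, 1L]
    jmax <- which.max(abs(v1))
    if (v1[jmax] < 0) v1 <- -v1
    score <- drop(zc %*% v1)
    if (all(abs(score) < 1e-12)) {
        set.seed(.deriveSeed(seed, "eminit"))
        score <- stats::runif(n, -1, 1)
    }
    resp <- cbind(ifelse(score <= 0, 0.8, 0.2),
                  ifelse(score <= 0, 0.2, 0.8))

    params <- NULL
    pi1 <- 0.5
    trace <- numeric(0)
    cur <- -Inf
    converged <- FALSE
    degenerate <- FALSE
    for (it in seq_len(maxIter)) {
        wk1 <- w * resp[, 1L]; wk2 <- w * resp[, 2L]
        pi1 <- sum(wk1) / sum(w)
        if (pi1 < 1e-8 || pi1 > 1 - 1e-8) { degenerate <- TRUE; break }
        newParams <- vector("list", 2L)
        for (k in 1:2) {
            wk <- if (k == 1L) wk1 else wk2
            a <- numeric(ncol(x)); b <- numeric(ncol(x))
            for (j in seq_len(ncol(x))) {
                fit <- tryCatch(weightedBetaFit(x[, j], wk),
                                error = function(e) NULL)
                if (is.null(fit)) { a[j] <- 1; b[j] <- 1 }
                else { a[j] <- fit$a; b[j] <- fit$b }
                if (!is.null(params)) {
                    oldll <- .wFeatureLL(x[, j], wk, params[[k]]$a[j],
                                         params[[k]]$b[j])
                    if (.wFeatureLL(x[, j], wk, a[j], b[j]) < oldll) {
                        a[j] <- params[[k]]$a[j]; b[j] <- params[[k]]$b[j]
                    }
                }
            }
            newParams[[k]] <- list(a = a, b = b)
        }
        params <- newParams
        lcomp <- cbind(log(pi1) + betaLoglik(x, params[[1L]]),
                       log1p(-pi1) + betaLoglik(x, params[[2L]]))
        lse <- .logRowSumExp(lcomp)
        new <- sum(w * lse)
        resp <- exp(lcomp - lse)
        trace <- c(trace, new)
        if (is.finite(cur) && abs(new - cur) <= tol * (abs(cur) + 1)) {
            cur <- new; converged <- TRUE; break
        }
        cur <- new
    }
    list(pi = pi1, params = params, resp = resp, loglik = cur,
         loglikTrace = trace, converged = converged, degenerate = degenerate)
}

#' BIC-gated split decision
#'
#' Compares the one-class and two-class models at a node by BIC computed on
#' the node's effective sample size (the sum of its fuzzy sample weights):
#' `BIC = -2 loglik + k log(nEffective)` with `k = 2 p` free parameters for
#' the single class and `k = 4 p + 1` for the two-class mixture (two beta
#' shapes per feature per class plus the mixture weight). The split is
#' accepted iff the two-class BIC is strictly smaller.
#'
#' @param loglikParent weighted log-likelihood of the one-class fit.
#' @param loglikChildren weighted log-likelihood of the two-class fit.
#' @param nEffective sum of sample weights at the node.
#' @param nFeatures number of features.
#' @return list with `accept` (logical), `bicParent`, `bicChildren`.
#' @export
splitDecision <- function(loglikParent, loglikChildren, nEffective,
                          nFeatures) {
    kParent <- 2 * nFeatures
    kChildren <- 4 * nFeatures + 1
    bicParent <- -2 * loglikParent + kParent * log(nEffective)
    bicChildren <- -2 * loglikChildren + kChildren * log(nEffective)
    list(accept = bicChildren < bicParent,
         bicParent = bicParent, bicChildren = bicChildren)
}

#' Fit a recursively partitioned beta-mixture model
#'
#' Starting from the root class "r" (every sample with weight 1), each node
#' is tentatively split by [emTwoClass()]; the split is kept iff it lowers
#' the node BIC ([splitDecision()]) and both children retain at least
#' `minClassSize` expected members. Children receive fuzzy weights (parent
#' weight times membership posterior) and are named by appending "L"/"R" to
#' the parent's name, so a leaf reached by a right then a left branch is
#' "rRL". Recursion also stops at `maxDepth`. Terminal classes are reported
#' in left-before-right traversal order and training-sample posteriors over
#' them are renormalized to sum to one.
#'
#' @param x numeric matrix, samples x features (named columns), values in
#'   \[0, 1\]; features must be non-constant after clamping.
#' @param minClassSize minimum expected class size; default 5.
#' @param maxDepth maximum tree depth; default 6.
#' @param seed integer seed (per-node EM seeds are derived from it and the
#'   node name, so fits are reproducible and sample-order invariant).
#' @return an [RPMMModel-class]
#' @export
fitRPMM <- function(x, minClassSize = 5, maxDepth = 6L, seed = 1L) {
    x <- as.matrix(x)
    if (nrow(x) < 2L || ncol(x) < 1L)
        stop("need at least 2 samples and 1 feature")
    if (any(!is.finite(x)) || any(x < 0 | x > 1))
        stop("all values must be finite and in [0, 1]")
    if (is.null(colnames(x)))
        colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
    constFeat <- apply(.clampUnit(x, .BETA_CLAMP), 2L, function(v)
        length(unique(v)) < 2L)
    if (any(constFeat))
        stop("constant feature(s) after clamping: ",
             paste(colnames(x)[constFeat], collapse = ", "))
    nTotal <- nrow(x)
    leafWeights <- list()

    grow <- function(w, name, depth) {
        fit1 <- .fitNodeParams(x, w)
        node <- list(name = name, weight = sum(w) / nTotal,
                     a = fit1$params$a, b = fit1$params$b, children = NULL)
        nEff <- sum(w)
        if (depth < maxDepth && nEff >= 2 * minClassSize) {
            em <- emTwoClass(x, sampleWeights = w,
                             seed = .deriveSeed(seed, name))
            if (!em$degenerate) {
                childSizes <- c(sum(w * em$resp[, 1L]),
                                sum(w * em$resp[, 2L]))
                dec <- splitDecision(fit1$loglik, em$loglik, nEff, ncol(x))
                if (dec$accept && all(childSizes >= minClassSize)) {
                    node$children <- list(
                        grow(w * em$resp[, 1L], paste0(name, "L"), depth + 1L),
                        grow(w * em$resp[, 2L], paste0(name, "R"), depth + 1L))
                    return(node)
                }
            }
        }
        leafWeights[[name]] <<- w
        node
    }
    root <- grow(rep(1, nTotal), "r", 0L)
    leaves <- .collectLeaves(root)
    classNames <- vapply(leaves, `[[`, character(1), "name")
    post <- do.call(cbind, leafWeights[classNames])
    colnames(post) <- classNames
    rownames(post) <- rownames(x)
    post <- post / rowSums(post)
    new("RPMMModel", root = root, featureIds = colnames(x),
        terminalClasses = classNames, trainPosteriors = post)
}

#' Empirical Bayes class posteriors for new samples
#'
#' Assigns samples to the fitted terminal methylation classes: the posterior
#' of class c is proportional to the class weight (its prior, learned from
#' the training fit) times the exponentiated product-beta log-likelihood
#' under the class parameters, normalized per sample. The hard label is the
#' posterior argmax; exact ties go to the lexicographically smallest class
#' name.
#'
#' @param model an [RPMMModel-class]
#' @param xNew numeric matrix, samples x features, in \[0, 1\]; columns must
#'   cover `model@featureIds` (extra columns are ignored, order is fixed).
#' @return list with `posterior` (samples x classes matrix, rows sum to 1)
#'   and `classes` (character vector of hard labels).
#' @export
posteriorClasses <- function(model, xNew) {
    stopifnot(is(model, "RPMMModel"))
    xNew <- as.matrix(xNew)
    missingFeat <- setdiff(model@featureIds, colnames(xNew))
    if (length(missingFeat))
        stop("feature(s) missing from new data: ",
             paste(missingFeat, collapse = ", "))
    xNew <- xNew[, model@featureIds, drop = FALSE]
    leaves <- .collectLeaves(model@root)
    priors <- vapply(leaves, `[[`, numeric(1), "weight")
    priors <- priors / sum(priors)
    lp <- vapply(leaves, function(lf)
        betaLoglik(xNew, list(a = lf$a, b = lf$b)), numeric(nrow(xNew)))
    lp <- matrix(lp, nrow = nrow(xNew))
    lp <- sweep(lp, 2L, log(priors), `+`)
    lse <- .logRowSumExp(lp)
    post <- exp(lp - lse)
    colnames(post) <- model@terminalClasses
    rownames(post) <- rownames(xNew)
    hard <- model@terminalClasses[max.col(post, ties.method = "first")]
    list(posterior = post, classes = hard)
}

.nodeToList <- function(node) {
    out <- list(name = node$name, weight = node$weight,
                a = node$a, b = node$b)
    if (!is.null(node$children))
        out$children <- list(.nodeToList(node$children[[1L]]),
                             .nodeToList(node$children[[2L]]))
    out
}

.nodeFromList <- function(lst) {
    node <- list(name = lst$name, weight = lst$weight,
                 a = as.numeric(lst$a), b = as.numeric(lst$b),
                 children = NULL)
    if (!is.null(lst$children))
        node$children <- list(.nodeFromList(lst$children[[1L]]),
                              .nodeFromList(lst$children[[2L]]))
    node
}

#' Serialize an RPMM model to JSON
#'
#' @param model an [RPMMModel-class]
#' @param path output JSON path.
#' @return invisibly, `path`. The round trip through [readRPMM()] reproduces
#'   identical predictions (training posteriors are not serialized).
#' @export
writeRPMM <- function(model, path) {
    obj <- list(featureIds = model@featureIds,
                tree = .nodeToList(model@root))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeRPMM
#' @export
readRPMM <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    root <- .nodeFromList(obj$tree)
    leaves <- .collectLeaves(root)
    nms <- vapply(leaves, `[[`, character(1), "name")
    new("RPMMModel", root = root,
        featureIds = as.character(obj$featureIds),
        terminalClasses = nms,
        trainPosteriors = matrix(numeric(0), 0, length(nms),
                                 dimnames = list(NULL, nms)))
}
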