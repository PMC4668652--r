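# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Conditional MLE odds ratio by grid maximization of the noncentral
# hypergeometric likelihood over log psi, refined around the grid optimum.
bruteConditionalOR <- function(tab) {
    x <- tab[1, 1]
    n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ]); m1 <- sum(tab[, 1])
    lo <- max(0, m1 - n2); hi <- min(n1, m1)
    supp <- lo:hi
    logw <- lchoose(n1, supp) + lchoose(n2, m1 - supp)
    condLL <- function(lp) {
        l <- logw + supp * lp
        x * lp - (max(l) + log(sum(exp(l - max(l)))))
    }
    grid <- seq(-15, 15, length.out = 4001)
    best <- grid[which.max(vapply(grid, condLL, numeric(1)))]
    fine <- seq(best - 0.01, best + 0.01, length.out = 2001)
    exp(fine[which.max(vapply(fine, condLL, numeric(1)))])
}

# AUC by counting all case-control score pairs (ties count one half).
bruteAUC <- function(scores, case) {
    xs <- scores[case == 1]; ys <- scores[case == 0]
    tot <- 0
    for (x in xs) for (y in ys)
        tot <- tot + (x > y) + 0.5 * (x == y)
    tot / (length(xs) * length(ys))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the non-zero differences.
enumSignedRankP <- function(d) {
    dnz <- d[d != 0]
    n <- length(dnz)
    if (n == 0) return(1)
    r <- rank(abs(dnz))
    W <- sum(r[dnz > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% r)
    pUp <- mean(Wall >= W); pLo <- mean(Wall <= W)
    min(1, 2 * min(pUp, pLo))
}

# Island means by brute-force interval scan (0-based half-open intervals).
bruteIslandMeans <- function(beta, pos, islStart, islEnd) {
    inIsl <- pos >= islStart & pos < islEnd
    if (!any(inIsl)) return(NULL)
    colMeans(beta[inIsl, , drop = FALSE])
}

# Small planted product-beta mixture: K archetype mean profiles, samples
# drawn with concentration conc. Returns samples x features matrix + labels.
plantedBetaClasses <- function(n, p, K, conc, seed, minSep = 0.2) {
    set.seed(seed)
    repeat {
        means <- matrix(runif(K * p, 0.15, 0.85), K, p)
        ok <- TRUE
        if (K > 1)
            for (i in seq_len(K - 1)) for (j in (i + 1):K)
                if (mean(abs(means[i, ] - means[j, ])) < minSep)
                    ok <- FALSE
        if (ok) break
    }
    cls <- rep_len(seq_len(K), n)
    x <- matrix(rbeta(n * p, means[cls, ] * conc,
                      (1 - means[cls, ]) * conc), n, p)
    colnames(x) <- sprintf("f%02d", seq_len(p))
    rownames(x) <- sprintf("s%03d", seq_len(n))
    list(x = x, labels = cls, means = means)
}

# Adjusted Rand index (independent implementation; mclust's version is used
# as a cross-check where available).
adjRandIndex <- function(a, b) {
    tab <- table(a, b)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
    nC2 <- choose(sum(tab), 2)
    expij <- ai * bj / nC2
    (sumij - expij) / ((ai + bj) / 2 - expij)
}

# Build a small cohort and its island matrix in one call.
makeCohort <- function(..., seed = 1) {
    cfg <- syntheticConfig(..., seed = seed)
    ds <- simulateCohort(cfg)
    im <- aggregateIslands(filterProbes(ds$probes), ds$annotation)
    list(ds = ds, im = im, samples = ds$samples, truth = ds$truth)
}
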