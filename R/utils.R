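# Shared numerical helpers (internal).

.clampUnit <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

.logit2 <- function(p) log2(p / (1 - p))

.expit2 <- function(m) 1 / (1 + 2^(-m))

# Row-wise log-sum-exp of a matrix.
.logRowSumExp <- function(lx) {
    mx <- apply(lx, 1L, max)
    mx + log(rowSums(exp(lx - mx)))
}

# Deterministic integer seed derived from a base seed and a node name,
# kept well below 2^31.
.deriveSeed <- function(seed, tag) {
    (as.integer(seed) %% 1000003L) * 1009L + sum(utf8ToInt(tag)) %% 9973L
}
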