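# Classifier performance: confusion tables, odds ratios, logistic models,
# ROC/AUC.

#' Confusion table from predicted methylation classes
#'
#' A sample is predicted positive iff its hard class label belongs to
#' `positiveClasses` (the case-heavy classes). Sensitivity and specificity
#' are returned as percentages.
#'
#' @param labels character vector of hard class labels.
#' @param case 0/1 case indicator, aligned with `labels`.
#' @param positiveClasses non-empty set of class names treated as predicted
#'   positive.
#' @return list with `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`.
#' @examples
#' confusionFromClasses(c("rRL", "rL", "rRL"), c(1, 0, 1), "rRL")
#' @export
confusionFromClasses <- function(labels, case, positiveClasses) {
    if (!length(labels)) stop("empty input")
    if (length(labels) != length(case))
        stop("labels and case must be aligned")
    if (!length(positiveClasses)) stop("positiveClasses must be non-empty")
    pred <- labels %in% positiveClasses
    tp <- sum(pred & case == 1); fp <- sum(pred & case == 0)
    fn <- sum(!pred & case == 1); tn <- sum(!pred & case == 0)
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp))
}

#' Exact (conditional) odds ratio for a 2x2 table
#'
#' Point estimate is the conditional maximum-likelihood odds ratio — the
#' value maximizing the noncentral hypergeometric likelihood given all table
#' margins — with the 95% confidence interval obtained by inverting the
#' exact test (both via [stats::fisher.test()]). The asymptotic
#' cross-product estimate `ad/bc` is reported alongside; zero cells yield
#' the 0 / +Inf sentinels.
#'
#' @param tab 2x2 matrix of non-negative integer counts, rows = exposed /
#'   unexposed, columns = case / control.
#' @return list with `or_cmle`, `ci_low`, `ci_high`, `p_exact`,
#'   `or_crossprod`.
#' @export
fisherExactOR <- function(tab) {
    tab <- as.matrix(tab)
    if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0) ||
        any(tab != round(tab)))
        stop("'tab' must be a 2x2 matrix of non-negative integer counts")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("all table margins must be positive")
    ft <- stats::fisher.test(tab)
    cp <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    list(or_cmle = unname(ft$estimate),
         ci_low = ft$conf.int[1L], ci_high = ft$conf.int[2L],
         p_exact = ft$p.value, or_crossprod = cp)
}

#' Unconditional logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit of case status on the supplied
#' predictors. Exponentiated coefficients are odds ratios with 95%
#' confidence intervals (Wald by default; `ciMethod = "profile"` inverts the
#' profile likelihood). Quasi-separation is reported via a flag when any
#' |log-odds| exceeds 10 rather than as an error.
#'
#' @param case 0/1 outcome.
#' @param design data.frame (or matrix) of predictors, e.g. a class-
#'   membership indicator and/or covariates.
#' @param ciMethod "wald" or "profile".
#' @return list with `coefficients` (data.frame: term, estimate (log-odds),
#'   se, or, or_low, or_high, z, p), `fitted` (per-sample probabilities),
#'   `separation` (logical flag), `fit` (the glm object).
#' @export
logisticModel <- function(case, design, ciMethod = c("wald", "profile")) {
    ciMethod <- match.arg(ciMethod)
    design <- as.data.frame(design)
    if (length(unique(case)) < 2L)
        stop("outcome must have both levels")
    if (length(case) <= ncol(design) + 1L)
        stop("need more samples than predictors")
    dat <- cbind(data.frame(.case = case), design)
    fit <- suppressWarnings(
        stats::glm(.case ~ ., data = dat, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    ci <- if (ciMethod == "wald") {
        suppressWarnings(stats::confint.default(fit))
    } else {
        suppressWarnings(suppressMessages(stats::confint(fit)))
    }
    ci <- ci[rownames(cf), , drop = FALSE]
    coefs <- data.frame(term = rownames(cf),
                        estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"],
                        or = exp(cf[, "Estimate"]),
                        or_low = exp(ci[, 1L]),
                        or_high = exp(ci[, 2L]),
                        z = cf[, "z value"],
                        p = cf[, "Pr(>|z|)"],
                        row.names = NULL, stringsAsFactors = FALSE)
    list(coefficients = coefs,
         fitted = stats::fitted(fit),
         separation = any(abs(cf[-1L, "Estimate"]) > 10),
         fit = fit)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties between a case and
#' a control score count one half); the curve enumerates all distinct score
#' thresholds from (0, 0) to (1, 1) and its trapezoidal area equals the
#' concordance AUC. The 95% CI uses the DeLong variance estimator based on
#' placement values, truncated to \[0, 1\].
#'
#' @param scores numeric risk scores (higher = more case-like), e.g. fitted
#'   probabilities.
#' @param case 0/1 outcome (both levels required).
#' @return list with `auc`, `ci_low`, `ci_high`, `curve` (data.frame of
#'   `fpr`, `tpr`).
#' @examples
#' rocAuc(c(1, 2, 3, 4), c(0, 1, 0, 1))  # AUC 0.75
#' @export
rocAuc <- function(scores, case) {
    if (length(scores) != length(case)) stop("inputs must be aligned")
    if (length(unique(case)) < 2L)
        stop("outcome must have both levels")
    xs <- scores[case == 1]; ys <- scores[case == 0]
    m <- length(xs); n <- length(ys)

    # placement values: V10[i] = P-hat(case i outscores a control)
    v10 <- vapply(xs, function(x) (sum(x > ys) + 0.5 * sum(x == ys)) / n,
                  numeric(1))
    v01 <- vapply(ys, function(y) (sum(xs > y) + 0.5 * sum(xs == y)) / m,
                  numeric(1))
    auc <- mean(v10)
    s10 <- if (m > 1) stats::var(v10) else 0
    s01 <- if (n > 1) stats::var(v01) else 0
    se <- sqrt(s10 / m + s01 / n)
    ciLow <- max(0, auc - stats::qnorm(0.975) * se)
    ciHigh <- min(1, auc + stats::qnorm(0.975) * se)

    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(xs >= t) / m, numeric(1))
    fpr <- vapply(thr, function(t) sum(ys >= t) / n, numeric(1))
    curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
    if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
        curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
    list(auc = auc, ci_low = ciLow, ci_high = ciHigh, curve = curve)
}
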