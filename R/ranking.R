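# Outcome-guided island ranking on the M-value scale.

#' Mixed-effects association of one island with case status
#'
#' Fits `y ~ case + age + sex + pack_years + alcohol + (1 | batch)` by REML
#' and returns the Wald t-statistic (estimate / standard error) of the case
#' indicator. With a single batch level the random intercept is dropped and
#' an ordinary least-squares fit is used (the two coincide when the
#' random-intercept variance is zero). Degenerate designs (constant y, or a
#' case coefficient that cannot be estimated) yield t = 0 with a flag;
#' mixed-model failures fall back to the fixed-effects-only fit.
#'
#' @param y numeric response (M-values of one island).
#' @param case 0/1 case indicator.
#' @param covars data.frame (or matrix) of adjustment covariates, typically
#'   age, sex, pack_years, alcohol; may be NULL for an unadjusted fit.
#' @param batch batch/processing-site labels (factor or character); NULL or
#'   a single level selects the OLS path.
#' @return list with `t` (Wald t-statistic) and `flag` ("ok", "degenerate",
#'   or "fallback_ols").
#' @export
fitIslandModel <- function(y, case, covars = NULL, batch = NULL) {
    n <- length(y)
    if (n < 10L) stop("need at least 10 samples")
    if (length(unique(case)) < 2L) stop("both case groups must be present")
    if (stats::sd(y) == 0)
        return(list(t = 0, flag = "degenerate"))
    dat <- data.frame(y = y, case = case)
    if (!is.null(covars)) dat <- cbind(dat, as.data.frame(covars))
    fixedTerms <- setdiff(names(dat), "y")
    fixedForm <- stats::reformulate(fixedTerms, response = "y")

    olsT <- function() {
        fit <- stats::lm(fixedForm, data = dat)
        cf <- summary(fit)$coefficients
        if (!"case" %in% rownames(cf) || !is.finite(cf["case", "t value"]))
            return(NULL)
        cf["case", "t value"]
    }

    useLmm <- !is.null(batch) && length(unique(batch)) > 1L
    if (useLmm) {
        dat$batch <- factor(batch)
        mmForm <- stats::as.formula(paste(
            "y ~", paste(fixedTerms, collapse = " + "), "+ (1 | batch)"))
        fit <- tryCatch(
            suppressMessages(suppressWarnings(
                lme4::lmer(mmForm, data = dat, REML = TRUE,
                           control = lme4::lmerControl(
                               calc.derivs = FALSE,
                               check.conv.singular = "ignore")))),
            error = function(e) NULL)
        if (!is.null(fit)) {
            cf <- stats::coef(summary(fit))
            if ("case" %in% rownames(cf) &&
                is.finite(cf["case", "t value"]))
                return(list(t = cf["case", "t value"], flag = "ok"))
        }
        tv <- olsT()
        if (is.null(tv)) return(list(t = 0, flag = "degenerate"))
        return(list(t = tv, flag = "fallback_ols"))
    }
    tv <- olsT()
    if (is.null(tv)) return(list(t = 0, flag = "degenerate"))
    list(t = tv, flag = "ok")
}

#' Rank CpG islands by case-status association
#'
#' Transforms island mean betas to M-values and fits [fitIslandModel()] per
#' island, ranking islands by the absolute t-statistic of case status
#' (rank 1 = largest). Samples with a missing covariate are excluded from
#' every island's fit (one consistent complete-case set); ties in the
#' absolute t-statistic are broken lexicographically by island id.
#'
#' @param im an [IslandMatrix-class]
#' @param ss sample-sheet data.frame (see [readSampleSheet()]); columns must
#'   be aligned with `im` samples by `sample_id`.
#' @param trainingOnly restrict to samples with `split == "train"`; default
#'   TRUE (requires a `split` column).
#' @param epsilon M-value clamp bound; default 1e-6.
#' @return data.frame with columns `island_id`, `t_stat`, `abs_t`, `rank`,
#'   `flag`, ordered by rank.
#' @export
rankIslands <- function(im, ss, trainingOnly = TRUE, epsilon = 1e-6) {
    stopifnot(is(im, "IslandMatrix"))
    ss <- validateSampleSheet(ss)
    if (nrow(im) < 2L) stop("need at least 2 islands to rank")
    if (trainingOnly) {
        if (!"split" %in% names(ss))
            stop("trainingOnly = TRUE requires a 'split' column")
        ss <- ss[!is.na(ss$split) & ss$split == "train", , drop = FALSE]
    }
    missingSamp <- setdiff(ss$sample_id, colnames(avgBeta(im)))
    if (length(missingSamp))
        stop("sample ", missingSamp[1L], " is absent from the island matrix")
    covCols <- c("case", "age", "sex", "pack_years", "alcohol", "batch")
    cc <- stats::complete.cases(ss[, covCols])
    ss <- ss[cc, , drop = FALSE]
    if (length(unique(ss$case)) < 2L)
        stop("both case groups must be present in the ranking set")
    M <- mValues(avgBeta(im)[, ss$sample_id, drop = FALSE], epsilon)
    covars <- ss[, c("age", "sex", "pack_years", "alcohol")]
    res <- lapply(seq_len(nrow(M)), function(i)
        fitIslandModel(M[i, ], ss$case, covars, ss$batch))
    out <- data.frame(island_id = rownames(M),
                      t_stat = vapply(res, `[[`, numeric(1), "t"),
                      flag = vapply(res, `[[`, character(1), "flag"),
                      stringsAsFactors = FALSE)
    if (all(out$flag == "degenerate"))
        stop("all island fits are degenerate")
    out$abs_t <- abs(out$t_stat)
    out <- out[order(-out$abs_t, out$island_id), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("island_id", "t_stat", "abs_t", "rank", "flag")]
}
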