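test_that("confusion tables follow the positive-class rule", {
    labels <- c(rep("rRL", 20), rep("rRRR", 13), rep("rL", 18),  # cases
                rep("rRL", 1), rep("rLL", 24))                    # controls
    case <- rep(c(1, 0), c(51, 25))
    conf <- confusionFromClasses(labels, case, c("rRL", "rRRR"))
    expect_identical(conf$tp, 33L)
    expect_identical(conf$fn, 18L)
    expect_identical(conf$fp, 1L)
    expect_identical(conf$tn, 24L)
    expect_equal(conf$tp + conf$fp + conf$fn + conf$tn, 76L)

    allPos <- confusionFromClasses(labels, case, unique(labels))
    expect_equal(allPos$sensitivity, 100)
    expect_equal(allPos$specificity, 0)

    perfect <- confusionFromClasses(c("A", "B"), c(1, 0), "A")
    expect_equal(perfect$sensitivity, 100)
    expect_equal(perfect$specificity, 100)
    expect_error(confusionFromClasses(character(0), integer(0), "A"),
                 "empty")
})

test_that("complementing the positive classes swaps sensitivity and specificity", {
    set.seed(2)
    labels <- sample(c("A", "B", "C"), 60, replace = TRUE)
    case <- rbinom(60, 1, 0.5)
    a <- confusionFromClasses(labels, case, "A")
    b <- confusionFromClasses(labels, 1 - case, c("B", "C"))
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$specificity, b$sensitivity)
})

test_that("exact odds ratios match the conditional-likelihood grid oracle", {
    tables <- list(matrix(c(33, 18, 1, 24), 2),
                   matrix(c(12, 5, 7, 20), 2),
                   matrix(c(8, 2, 3, 9), 2),
                   matrix(c(4, 11, 9, 6), 2))
    for (tab in tables) {
        res <- fisherExactOR(tab)
        oracle <- bruteConditionalOR(tab)
        expect_equal(res$or_cmle, oracle, tolerance = 5e-3)
        expect_lte(res$ci_low, res$or_cmle)
        expect_gte(res$ci_high, res$or_cmle)
    }
    sym <- fisherExactOR(matrix(c(5, 5, 5, 5), 2))
    expect_equal(sym$or_cmle, 1.0, tolerance = 1e-8)

    sep <- fisherExactOR(matrix(c(3, 0, 0, 3), 2))
    expect_identical(sep$or_cmle, Inf)
    expect_true(is.finite(sep$ci_low) && sep$ci_low > 0)
    expect_error(fisherExactOR(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("logistic regression reproduces the cross-product OR and recovers truth", {
    # saturated 2x2: exp(coef) equals ad/bc
    tab <- matrix(c(20, 10, 8, 25), 2)      # exposed/unexposed x case/control
    exposure <- rep(c(1, 0, 1, 0), c(20, 10, 8, 25))
    case <- rep(c(1, 1, 0, 0), c(20, 10, 8, 25))
    fit <- logisticModel(case, data.frame(exposure = exposure))
    orHat <- fit$coefficients$or[fit$coefficients$term == "exposure"]
    expect_equal(orHat, (20 * 25) / (8 * 10), tolerance = 1e-6)

    # independent predictor: OR ~ 1
    set.seed(5)
    x <- rnorm(4000); y <- rbinom(4000, 1, 0.4)
    fitNull <- logisticModel(y, data.frame(x = x))
    expect_equal(fitNull$coefficients$or[2], 1, tolerance = 0.15)
    expect_false(fitNull$separation)

    # known coefficients recovered within 2 SE
    set.seed(6)
    x1 <- rnorm(2000); x2 <- rbinom(2000, 1, 0.5)
    eta <- -0.5 + 0.8 * x1 - 0.6 * x2
    y2 <- rbinom(2000, 1, plogis(eta))
    fit2 <- logisticModel(y2, data.frame(x1 = x1, x2 = x2))
    cf <- fit2$coefficients
    expect_lt(abs(cf$estimate[cf$term == "x1"] - 0.8),
              2 * cf$se[cf$term == "x1"])
    expect_lt(abs(cf$estimate[cf$term == "x2"] + 0.6),
              2 * cf$se[cf$term == "x2"])
    expect_true(all(fit2$fitted > 0 & fit2$fitted < 1))

    # perfect separation flags rather than crashes
    sepFit <- logisticModel(c(0, 0, 0, 1, 1, 1),
                            data.frame(x = c(0, 0, 0, 1, 1, 1)))
    expect_true(sepFit$separation)
})

test_that("AUC equals brute-force pair counting on small inputs", {
    expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
    expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
    expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

    set.seed(7)
    for (i in 1:25) {
        n <- sample(4:20, 1)
        scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
        case <- c(0, 1, rbinom(n - 2, 1, 0.5))
        res <- rocAuc(scores, case)
        expect_equal(res$auc, bruteAUC(scores, case), tolerance = 1e-12)
        # curve contract: endpoints, monotonicity, trapezoid area == auc
        cv <- res$curve
        expect_equal(cv[1, ], data.frame(fpr = 0, tpr = 0))
        expect_equal(as.numeric(cv[nrow(cv), ]), c(1, 1))
        expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
        trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
        expect_equal(trap, res$auc, tolerance = 1e-10)
    }
})

test_that("AUC is invariant under strictly increasing score transforms", {
    set.seed(8)
    scores <- rnorm(50); case <- rbinom(50, 1, 0.5)
    a1 <- rocAuc(scores, case)$auc
    expect_equal(rocAuc(exp(scores), case)$auc, a1)
    expect_equal(rocAuc(rank(scores), case)$auc, a1)
    expect_error(rocAuc(scores, rep(1, 50)), "both levels")
})

test_that("AUC and DeLong interval agree with pROC", {
    skip_if_not_installed("pROC")
    set.seed(9)
    scores <- c(rnorm(40, 1), rnorm(60))
    case <- rep(c(1, 0), c(40, 60))
    res <- rocAuc(scores, case)
    pr <- pROC::roc(case, scores, quiet = TRUE, direction = "<")
    expect_equal(res$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(res$ci_low, ci[1], tolerance = 1e-6)
    expect_equal(res$ci_high, ci[3], tolerance = 1e-6)
})
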