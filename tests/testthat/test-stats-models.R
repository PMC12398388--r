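test_that("the mixed model recovers exact coefficients in the noise-free limit", {
    tab <- simLmmTable(nPart = 12, sdRan = 0, sdRes = 0, seed = 2)
    fit <- fitLmm(tab, "anxiety")
    beta <- c(0.1, 0.05, -0.03, -0.02, -0.04, 0.02)
    expect_lt(max(abs(fixedEffects(fit)$estimate - beta)), 1e-6)
    expect_identical(fit@nObs, 36L)
    expect_identical(fit@nGroups, 12L)
})

test_that("fixed effects equal the OLS solution on balanced data", {
    tab <- simLmmTable(nPart = 20, sdRan = 0.03, sdRes = 0.05, seed = 3)
    fit <- fitLmm(tab, "anxiety")
    d <- tab
    d$condition <- factor(d$condition, c("Negative", "Reappraise", "Suppress"))
    d$att <- d$anxiety - mean(d$anxiety)
    ols <- lm(dwpli ~ condition * att, data = d)
    expect_lt(max(abs(fixedEffects(fit)$estimate - coef(ols))), 1e-8)
})

test_that("term labels follow the reporting convention with Negative as reference", {
    tab <- simLmmTable(nPart = 10, seed = 4)
    fit <- fitLmm(tab, "anxiety")
    expect_setequal(fixedEffects(fit)$label,
                    c("Intercept", "Condition: Reappraise",
                      "Condition: Suppress", "Attachment Anxiety",
                      "Reappraise × Anxiety", "Suppress × Anxiety"))
    fitAv <- fitLmm(tab, "avoidance")
    expect_true("Suppress × Avoidance" %in% fixedEffects(fitAv)$label)
    expect_error(fitLmm(tab[tab$condition == "Negative", ], "anxiety"),
                 "two conditions")
    expect_error(fitLmm(tab[, setdiff(names(tab), "anxiety")], "anxiety"),
                 "anxiety")
})

test_that("fit criteria are internally consistent and validity-checked", {
    tab <- simLmmTable(nPart = 15, seed = 5)
    fit <- fitLmm(tab, "anxiety")
    expect_equal(fit@deviance, -2 * fit@logLik)
    expect_equal(fit@aic, -2 * fit@logLik + 2 * fit@nPar)
    expect_gte(fit@ranVar, 0)
    expect_gt(fit@resVar, 0)
    expect_identical(fit@nPar, 8L)   # 6 fixed + 2 variance components
})

test_that("planted interaction signs are recovered across replicate model tables", {
    hits <- 0L
    for (r in 1:20) {
        tab <- simLmmTable(nPart = 60,
                           beta = c(0.1, 0.08, 0, -0.01, -0.03, 0),
                           sdRan = 0.04, sdRes = 0.06, seed = 100 + r)
        fx <- fixedEffects(fitLmm(tab, "anxiety"))
        if (fx$estimate[fx$label == "Reappraise × Anxiety"] < 0)
            hits <- hits + 1L
    }
    expect_gte(hits, 16L)
})

test_that("Wald CIs cover and fixed effects are nearly unbiased over replicates", {
    beta <- c(0.1, 0.08, -0.05, -0.02, -0.03, 0.02)
    est <- matrix(0, 20, 6)
    cover <- 0L; total <- 0L
    for (r in 1:20) {
        tab <- simLmmTable(nPart = 60, beta = beta, sdRan = 0.04,
                           sdRes = 0.05, seed = 400 + r)
        fx <- fixedEffects(fitLmm(tab, "anxiety"))
        est[r, ] <- fx$estimate
        cover <- cover + sum(fx$ciLow <= beta & beta <= fx$ciHigh)
        total <- total + 6L
    }
    bias <- abs(colMeans(est) - beta)
    expect_true(all(bias <= pmax(0.1 * abs(beta), 0.005)))
    expect_gte(cover / total, 0.88)
    expect_lte(cover / total, 0.99)
})

test_that("the interaction false-positive rate is controlled under the null", {
    sig <- 0L
    nrep <- 100L
    for (r in seq_len(nrep)) {
        tab <- simLmmTable(nPart = 60, beta = c(0.1, 0.08, -0.05, 0, 0, 0),
                           sdRan = 0.04, sdRes = 0.05, seed = 700 + r)
        fx <- fixedEffects(fitLmm(tab, "anxiety"))
        if (fx$p[fx$label == "Reappraise × Anxiety"] < 0.05) sig <- sig + 1L
    }
    expect_lte(sig, ceiling(0.10 * nrep))
})

test_that("likelihood-ratio tests behave on identical, nested and non-nested fits", {
    tab <- simLmmTable(nPart = 20, seed = 6)
    full <- fitLmm(tab, "anxiety")
    same <- fitLmm(tab, "anxiety")
    lrt0 <- likelihoodRatioTest(same, full)
    expect_equal(lrt0$statistic, 0)
    expect_identical(lrt0$df, 0L)
    expect_equal(lrt0$p.value, 1)

    nested <- fitLmm(tab, "anxiety", fixedTerms = c("condition", "attachment"))
    lrt <- likelihoodRatioTest(nested, full)
    expect_identical(lrt$df, 2L)    # two interaction coefficients dropped
    expect_gte(lrt$statistic, 0)

    condOnly <- fitLmm(tab, "anxiety", fixedTerms = "condition")
    expect_error(likelihoodRatioTest(full, condOnly), "nested")
})

test_that("the LRT statistic is non-negative over random nested fits", {
    for (r in 1:50) {
        tab <- simLmmTable(nPart = 12, beta = rnorm(6, 0, 0.05),
                           sdRan = 0.03, sdRes = 0.05, seed = 900 + r)
        full <- fitLmm(tab, "anxiety")
        nested <- fitLmm(tab, "anxiety",
                         fixedTerms = sample(list(c("condition", "attachment"),
                                                  "condition", "attachment"), 1)[[1]])
        expect_gte(likelihoodRatioTest(nested, full)$statistic, 0)
    }
})

test_that("BH adjustment matches the brute-force step-up computation", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(0.3), 0.3)
    expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
    set.seed(10)
    for (i in 1:50) {
        p <- runif(sample(1:20, 1))
        expect_equal(bhFdr(p), bruteBH(p))
    }
    p <- runif(10)
    expect_true(all(bhFdr(p) >= p))
    expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("the Shapiro-Wilk gate flags skew and passes normal samples", {
    set.seed(2)
    flagged <- sum(vapply(1:100, function(i)
        shapiroWilkGate(rexp(60))$useNonparametric, TRUE))
    expect_gte(flagged, 95)
    W <- vapply(1:100, function(i) shapiroWilkGate(rnorm(60))$W, 0)
    expect_gt(median(W), 0.95)
    expect_error(shapiroWilkGate(rep(1, 10)), "identical")
    expect_error(shapiroWilkGate(c(1, 2)), "3..5000")
})

test_that("Friedman statistic matches theory, the base oracle, and handles ties", {
    # perfect concordance: chi^2 = n (k - 1)
    m <- matrix(rep(c(1, 2, 3, 4), each = 60), 60) +
        matrix(rnorm(240, 0, 1e-3), 60)
    m <- t(apply(m, 1, sort))
    ft <- friedmanTest(m)
    expect_equal(ft$statistic, 180)
    expect_equal(ft$df, 3)

    # identical columns: all ties, statistic 0, p = 1
    ft0 <- friedmanTest(matrix(rep(1:5, 3), 5))
    expect_equal(ft0$statistic, 0)
    expect_equal(ft0$p.value, 1)

    # tied toy matrix agrees with stats::friedman.test and the definition
    m3 <- matrix(c(1, 2, 3, 1, 1, 3, 2, 2, 2), 3, byrow = TRUE)
    ft3 <- friedmanTest(m3)
    expect_equal(ft3$statistic,
                 unname(stats::friedman.test(m3)$statistic))
    expect_equal(ft3$statistic, bruteFriedman(m3))

    set.seed(4)
    for (i in 1:10) {
        mm <- matrix(sample(1:5, 16, replace = TRUE), 4)
        expect_equal(friedmanTest(mm)$statistic, bruteFriedman(mm))
    }
    expect_error(friedmanTest(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("Dunn post-hoc z values match the hand oracle and respect symmetry", {
    set.seed(9)
    m <- matrix(runif(24, 1, 7), 6, 4,
                dimnames = list(NULL, c("Neu", "Neg", "Rea", "Sup")))
    du <- dunnPosthoc(m)
    expect_identical(nrow(du), 6L)
    for (r in seq_len(nrow(du))) {
        u <- match(du$group1[r], colnames(m))
        v <- match(du$group2[r], colnames(m))
        expect_equal(du$z[r], bruteDunnZ(m, u, v))
    }
    # swapping two condition columns negates their z
    m2 <- m[, c(2, 1, 3, 4)]
    colnames(m2) <- colnames(m)[c(2, 1, 3, 4)]
    du2 <- dunnPosthoc(m2)
    expect_equal(du2$z[1], -du$z[1])

    # identical columns: z = 0, adjusted p capped at 1
    mId <- matrix(rep(1:6, 3), 6)
    duId <- dunnPosthoc(mId)
    expect_true(all(duId$z == 0))
    expect_true(all(duId$pAdj == 1))
    expect_true(all(du$pAdj >= du$p & du$pAdj <= 1))
})

test_that("paired Cohen's d follows the difference-score convention", {
    set.seed(14)
    x <- rnorm(1e4); y <- x - rnorm(1e4, 0.5, 1)
    expect_equal(cohensDPaired(x, y), 0.5, tolerance = 0.05)
    expect_error(cohensDPaired(x, x), "zero SD")
    expect_error(cohensDPaired(x, x + 2), "zero SD")   # constant shift
    expect_error(cohensDPaired(1:3, 1:4), "equal length")
})

test_that("RM-ANOVA power is monotone in n and solves the design numbers", {
    pows <- vapply(10:100, function(N)
        rmAnovaPowerValue(N, k = 3, f = 0.2), 0)
    expect_true(all(diff(pows) > 0))
    expect_identical(rmAnovaPower(k = 3, f = 0.20), 48L)
    expect_equal(round(rmAnovaPower(k = 3, n = 60, solveFor = "f"), 2), 0.18)
    expect_error(rmAnovaPower(k = 3, f = 1e-6), "unreachable")
    expect_error(rmAnovaPowerValue(20, 3, 0.2, rho = 1.2), "rho")
})
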