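mkConn <- function(m, participant, condition, band = "theta") {
    diag(m) <- NA
    new("ConnMatrix", participant = participant, condition = condition,
        band = band, matrix = m, nObs = 10L, nUndefined = 0L)
}
symMat <- function(v, labels) {
    n <- length(labels)
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    m[upper.tri(m)] <- v
    m + t(m)
}

test_that("delta matrices subtract the baseline per participant", {
    labs <- c("A", "B", "C")
    base <- symMat(c(0.2, 0.3, 0.4), labs)
    conn <- list(mkConn(base, "P01", "NatNeutral"),
                 mkConn(base, "P01", "Reappraise"),
                 mkConn(base + 0.1, "P01", "Suppress"))
    d <- deltaMatrices(conn)
    expect_setequal(vapply(d, condition, ""), c("Reappraise", "Suppress"))
    expect_equal(connValues(d[["P01.Reappraise.theta"]])["A", "B"], 0)
    expect_equal(connValues(d[["P01.Suppress.theta"]])["A", "B"], 0.1)

    expect_error(deltaMatrices(list(mkConn(base, "P02", "Reappraise"))),
                 "P02")
})

test_that("group deltas average participants with NaN exclusion", {
    labs <- c("A", "B")
    m1 <- symMat(0.1, labs); m2 <- symMat(0.3, labs)
    conn <- list(mkConn(symMat(0, labs), "P01", "NatNeutral"),
                 mkConn(m1, "P01", "Reappraise"),
                 mkConn(symMat(0, labs), "P02", "NatNeutral"),
                 mkConn(m2, "P02", "Reappraise"))
    g <- groupDelta(deltaMatrices(conn))
    expect_equal(connValues(g[["Reappraise.theta"]])["A", "B"], 0.2)

    conn[[4]]@matrix["A", "B"] <- NaN
    conn[[4]]@matrix["B", "A"] <- NaN
    suppressMessages(g2 <- groupDelta(deltaMatrices(conn)))
    expect_equal(connValues(g2[["Reappraise.theta"]])["A", "B"], 0.1)
})

test_that("the positive-pool percentile follows the midpoint convention", {
    labs <- paste0("c", 1:7)   # 21 upper-triangle entries
    vals <- c(seq(0.01, 0.20, by = 0.01), -0.5)
    dm <- new("DeltaMatrix", participant = "P01", condition = "Reappraise",
              band = "theta", matrix = symMat(vals, labs), nObs = 1L,
              nUndefined = 0L, baseline = "NatNeutral")
    thr <- positivePercentileThreshold(list(dm), q = 95)
    expect_equal(unname(thr["theta"]),
                 bruteMidpointPercentile(seq(0.01, 0.20, by = 0.01), 95))
    expect_equal(unname(thr["theta"]), 0.195)

    # all positives equal -> threshold equals that constant
    dmc <- new("DeltaMatrix", participant = "P01", condition = "Reappraise",
               band = "theta", matrix = symMat(rep(0.07, 21), labs),
               nObs = 1L, nUndefined = 0L, baseline = "NatNeutral")
    expect_equal(unname(positivePercentileThreshold(list(dmc))["theta"]), 0.07)

    dmneg <- new("DeltaMatrix", participant = "P01", condition = "Reappraise",
                 band = "theta", matrix = symMat(rep(-0.1, 21), labs),
                 nObs = 1L, nUndefined = 0L, baseline = "NatNeutral")
    expect_error(positivePercentileThreshold(list(dmneg)), "positive")
})

test_that("percentile agrees with the brute-force oracle on random pools", {
    set.seed(5)
    labs <- paste0("c", 1:6)
    for (i in 1:20) {
        v <- round(runif(15, -0.2, 0.4), 3)
        if (!any(v > 0)) v[1] <- 0.1
        dm <- new("DeltaMatrix", participant = "P01", condition = "Reappraise",
                  band = "theta", matrix = symMat(v, labs), nObs = 1L,
                  nUndefined = 0L, baseline = "NatNeutral")
        for (q in c(80, 90, 95, 99))
            expect_equal(unname(positivePercentileThreshold(list(dm), q)["theta"]),
                         bruteMidpointPercentile(v[v > 0], q))
    }
})

test_that("threshold is invariant to participant and condition order", {
    labs <- paste0("c", 1:5)
    set.seed(11)
    dms <- lapply(1:6, function(i)
        new("DeltaMatrix", participant = sprintf("P%02d", (i - 1) %/% 2 + 1),
            condition = c("Reappraise", "Suppress")[(i - 1) %% 2 + 1],
            band = "theta", matrix = symMat(rnorm(10, 0.05, 0.1), labs),
            nObs = 1L, nUndefined = 0L, baseline = "NatNeutral"))
    t1 <- positivePercentileThreshold(dms)
    t2 <- positivePercentileThreshold(rev(dms))
    expect_identical(t1, t2)
})

test_that("masking keeps strictly suprathreshold pairs and is idempotent", {
    labs <- paste0("c", 1:4)
    m <- symMat(c(0.02, 0.05, 0.09, 0, -0.01, 0.03), labs)
    gd <- new("DeltaMatrix", participant = "group", condition = "Reappraise",
              band = "theta", matrix = m, nObs = 0L, nUndefined = 0L,
              baseline = "NatNeutral")
    mk <- applyMask(gd, 0.04)
    expect_equal(nrow(pairList(mk)), 2L)    # 0.05 and 0.09
    expect_equal(countSuprathreshold(m, 0.04), 2L)
    expect_true(all(pairList(mk)$delta > 0.04))
    mm <- maskedMatrix(mk)
    expect_identical(mm, t(mm))

    # idempotence
    gd2 <- gd; gd2@matrix <- mm
    mk2 <- applyMask(gd2, 0.04)
    expect_identical(maskedMatrix(mk2), mm)
    expect_equal(pairList(mk2)$delta, pairList(mk)$delta)

    # threshold above the maximum empties the mask
    mkHigh <- applyMask(gd, 1)
    expect_identical(nrow(pairList(mkHigh)), 0L)
    expect_true(all(maskedMatrix(mkHigh) == 0))

    # ties at the threshold are excluded (strict >)
    mkTie <- applyMask(gd, 0.09)
    expect_identical(nrow(pairList(mkTie)), 0L)
})

test_that("pair counts match brute-force enumeration and fall as q rises", {
    set.seed(3)
    labs <- paste0("c", 1:8)
    dms <- lapply(1:5, function(i)
        new("DeltaMatrix", participant = sprintf("P%02d", i),
            condition = "Reappraise", band = "theta",
            matrix = symMat(rnorm(28, 0.02, 0.08), labs), nObs = 1L,
            nUndefined = 0L, baseline = "NatNeutral"))
    g <- groupDelta(dms)[["Reappraise.theta"]]
    counts <- integer(0)
    for (q in c(80, 90, 95, 99)) {
        thr <- positivePercentileThreshold(dms, q)["theta"]
        mk <- applyMask(g, thr, q = q)
        expect_equal(nrow(pairList(mk)),
                     countSuprathreshold(connValues(g), thr))
        counts <- c(counts, nrow(pairList(mk)))
    }
    expect_true(all(diff(counts) <= 0))
})

test_that("individual and group pooling modes give their respective thresholds", {
    labs <- paste0("c", 1:4)
    d1 <- new("DeltaMatrix", participant = "P01", condition = "Reappraise",
              band = "theta", matrix = symMat(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), labs),
              nObs = 1L, nUndefined = 0L, baseline = "NatNeutral")
    d2 <- new("DeltaMatrix", participant = "P02", condition = "Reappraise",
              band = "theta", matrix = symMat(rep(0.1, 6), labs),
              nObs = 1L, nUndefined = 0L, baseline = "NatNeutral")
    indiv <- positivePercentileThreshold(list(d1, d2), 95)
    grp <- positivePercentileThreshold(groupDelta(list(d1, d2)), 95)
    expect_equal(unname(indiv["theta"]),
                 bruteMidpointPercentile(c(seq(0.1, 0.6, by = 0.1),
                                           rep(0.1, 6)), 95))
    expect_equal(unname(grp["theta"]),
                 bruteMidpointPercentile((seq(0.1, 0.6, by = 0.1) + 0.1) / 2, 95))
    expect_false(indiv["theta"] == grp["theta"])
})

test_that("ROI metrics average masked pairs touching the ROI without double counting", {
    mont <- montage(c("Fz", "FC1", "Cz", "Pz", "Oz"),
                    roiMap = list(frontal = c("Fz", "FC1"), central = "Cz"))
    pl <- data.frame(chanA = c("Fz", "Cz", "Fz"),
                     chanB = c("Pz", "Oz", "FC1"),
                     delta = c(0.2, 0.15, 0.3), stringsAsFactors = FALSE)
    labs <- chanLabels(mont)
    m <- matrix(0, 5, 5, dimnames = list(labs, labs))
    m["Fz", "Pz"] <- m["Pz", "Fz"] <- 0.1
    m["Cz", "Oz"] <- m["Oz", "Cz"] <- 0.5
    m["Fz", "FC1"] <- m["FC1", "Fz"] <- 0.2
    dm <- new("DeltaMatrix", participant = "P01", condition = "Reappraise",
              band = "theta", matrix = m, nObs = 1L, nUndefined = 0L,
              baseline = "NatNeutral")
    met <- roiMetrics(list(dm), pl, mont)
    frontal <- met[met$roi == "frontal", ]
    # qualifying frontal pairs: (Fz,Pz) and (Fz,FC1) once each; not (Cz,Oz)
    expect_equal(frontal$nPairs, 2L)
    expect_equal(frontal$dwpli, mean(c(0.1, 0.2)))
    central <- met[met$roi == "central", ]
    expect_equal(central$dwpli, 0.5)

    # empty qualifying set -> missing value with a warning
    mont2 <- montage(chanLabels(mont),
                     roiMap = list(frontal = c("Fz", "FC1"), empty = "Oz"))
    pl2 <- pl[3, ]   # only (Fz, FC1): nothing touches Oz
    expect_warning(met2 <- roiMetrics(list(dm), pl2, mont2), "empty")
    expect_true(is.na(met2$dwpli[met2$roi == "empty"]))
})

test_that("the model table has the documented schema and study-design row count", {
    participants <- sampleCohort(60, seed = 20)
    metrics <- expand.grid(participant = participants$id,
                           condition = c("Negative", "Reappraise", "Suppress"),
                           stringsAsFactors = FALSE)
    metrics$band <- "theta"; metrics$roi <- "frontal"
    metrics$dwpli <- rnorm(nrow(metrics)); metrics$nPairs <- 3L
    tab <- buildModelTable(metrics, participants)
    expect_identical(nrow(tab), 180L)   # 60 participants x 3 conditions
    expect_identical(names(tab),
                     c("participant", "condition", "band", "roi", "dwpli",
                       "anxiety", "avoidance", "nPairs"))
    metrics$participant[1] <- "P99"
    expect_error(buildModelTable(metrics, participants), "P99")
})
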