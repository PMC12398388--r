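# Independent oracles and small fixtures used across the suite.

# Midpoint-position percentile: p_k = (k - 0.5)/n with linear interpolation
# between adjacent order statistics, clamped at the extremes.  Written
# directly from the definition, independent of stats::quantile.
bruteMidpointPercentile <- function(x, q) {
    x <- sort(x)
    n <- length(x)
    p <- q / 100
    pk <- (seq_len(n) - 0.5) / n
    if (p <= pk[1]) return(x[1])
    if (p >= pk[n]) return(x[n])
    k <- max(which(pk <= p))
    x[k] + (p - pk[k]) / (pk[k + 1] - pk[k]) * (x[k + 1] - x[k])
}

# Step-up BH adjustment evaluated directly as min over tails of p_(j)*m/j.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- vapply(seq_len(m), function(i)
        min(1, min(ps[i:m] * m / (i:m))), 0)
    out <- numeric(m)
    out[o] <- adj
    out
}

# Friedman statistic recomputed from the definition on midranks (independent
# code path from the package's implementation).
bruteFriedman <- function(m) {
    r <- t(apply(m, 1, rank))
    n <- nrow(r); k <- ncol(r)
    num <- (k - 1) * sum((colSums(r) - n * (k + 1) / 2)^2)
    den <- sum((r - (k + 1) / 2)^2)
    if (den == 0) 0 else num / den
}

# Dunn z for one condition pair, from rank sums and the per-block
# permutation variance, written out elementwise.
bruteDunnZ <- function(m, u, v) {
    r <- t(apply(m, 1, rank))
    k <- ncol(r)
    varDiff <- 0
    for (i in seq_len(nrow(r))) {
        s2 <- sum((r[i, ] - mean(r[i, ]))^2) / k
        varDiff <- varDiff + 2 * s2 * k / (k - 1)
    }
    diffs <- sum(r[, u]) - sum(r[, v])
    if (diffs == 0) 0 else diffs / sqrt(varDiff)
}

# Small two-ROI montage for synthetic tests.
miniMontage <- function(n = 8) {
    labs <- c("Fz", "F3", "Cz", "C3", "Pz", "Oz", "P3", "P4")[seq_len(n)]
    montage(labs,
            roiMap = list(frontal = intersect(c("Fz", "F3"), labs),
                          central = intersect(c("Cz", "C3"), labs)))
}

# Fast design for unit tests: short epochs still spanning the standard
# analysis window.
quickDesign <- function(trials = 10, srate = 100, snr = 1, mixing = NULL,
                        conditions = "NatNeutral", bands = defaultBands()) {
    designSpec(trialsPerCondition = trials, srate = srate, snr = snr,
               mixing = mixing, conditions = conditions, bands = bands)
}

# Simulate a long-format model table directly from the mixed-model
# generative equation with known coefficients.
simLmmTable <- function(nPart = 60, beta = c(0.1, 0.05, -0.03, -0.02, -0.04, 0.02),
                        sdRan = 0.05, sdRes = 0.05, seed = 1) {
    set.seed(seed)
    d <- expand.grid(participant = sprintf("P%02d", seq_len(nPart)),
                     condition = c("Negative", "Reappraise", "Suppress"),
                     stringsAsFactors = FALSE)
    anx <- rnorm(nPart, 0, 1.2)
    b0 <- rnorm(nPart, 0, sdRan)
    i <- as.integer(factor(d$participant))
    d$anxiety <- anx[i] + 3.5
    d$avoidance <- rnorm(nrow(d)) + 3.5
    att <- d$anxiety - mean(d$anxiety)
    condF <- factor(d$condition, c("Negative", "Reappraise", "Suppress"))
    X <- model.matrix(~ condF * att)
    d$dwpli <- as.vector(X %*% beta) + b0[i] + rnorm(nrow(d), 0, sdRes)
    d$band <- "theta"; d$roi <- "frontal"; d$nPairs <- 2L
    d
}

# Cohort configuration used by the replicate simulation studies: the study
# design at reduced problem size (12-channel montage, 8 trials, 200 Hz,
# theta+beta bands).  `null = TRUE` keeps the condition effects but removes
# every attachment slope.
cohortConfig <- function(seed, null = FALSE, bands = list(theta = c(4, 8),
                                                          beta = c(15, 30)),
                         predictors = c("anxiety", "avoidance")) {
    slopeTh <- if (null) NULL else list(Reappraise = -0.7)
    slopeBe <- if (null) NULL else list(Suppress = 0.7)
    edges <- list(
        list(pair = c("Fz", "Pz"), band = "theta", baseLag = pi / 2,
             intercept = -1, offsets = list(Reappraise = 2),
             slopes = slopeTh, dimension = "anxiety"),
        list(pair = c("F4", "Oz"), band = "theta", baseLag = pi / 3,
             intercept = -1, offsets = list(Reappraise = 2),
             slopes = slopeTh, dimension = "anxiety"),
        list(pair = c("Cz", "Pz"), band = "beta", baseLag = pi / 2,
             intercept = -1, offsets = list(Suppress = 1.5),
             slopes = slopeBe, dimension = "avoidance"),
        list(pair = c("C3", "Oz"), band = "beta", baseLag = 2 * pi / 3,
             intercept = -1, offsets = list(Suppress = 1.5),
             slopes = slopeBe, dimension = "avoidance"))
    edges <- Filter(function(e) e$band %in% names(bands), edges)
    validateConfig(list(
        seed = as.integer(seed),
        simulate = list(
            nParticipants = 60L, trialsPerCondition = 8L, srate = 200,
            montage = "reduced", edges = edges),
        bands = bands,
        model = list(predictors = predictors)))
}

# One pipeline run on a scratch directory; returns the effects table.
runCohort <- function(cfg) {
    od <- file.path(tempdir(), paste0("coh_", cfg$seed, "_",
                                      substr(pcConfHash(cfg), 1, 6)))
    rep <- runPipeline(cfg, outDir = od, verbose = FALSE)
    unlink(od, recursive = TRUE)
    rep
}

pcConfHash <- function(cfg) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
    unname(tools::md5sum(tmp))
}
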