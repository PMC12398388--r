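#' Reduced 12-channel montage
#'
#' A compact montage for fast simulation studies: 5 frontal and 5 central
#' ROI electrodes plus Pz and Oz.  The full study montage is
#' [defaultMontage()].
#'
#' @return a [Montage].
#' @export
reducedMontage <- function() {
    frontal <- c("Fz", "F3", "F4", "FC1", "FC2")
    central <- c("Cz", "C3", "C4", "CP1", "CP2")
    montage(c(frontal, central, "Pz", "Oz"),
            roiMap = list(frontal = frontal, central = central))
}

pcDefaultConfig <- function() {
    list(
        seed = 1L,
        simulate = list(
            nParticipants = 60L, trialsPerCondition = 15L, srate = 500,
            t0 = -1.0, duration = 5.0, snr = 1, dropout = FALSE,
            mixingLeakage = 0.1, anxietyMean = 3.5, anxietySd = 1.2,
            avoidanceMean = 3.5, avoidanceSd = 1.2, correlation = 0,
            montage = "default", edges = "default", writeEpochs = FALSE),
        spectral = list(halfBandwidth = 2, windowStart = 0.3, windowEnd = 4.0),
        bands = list(delta = c(1, 3), theta = c(4, 8), alpha = c(9, 12),
                     beta = c(15, 30)),
        mask = list(q = 95, pooling = "individual", baseline = "NatNeutral"),
        model = list(predictors = c("anxiety", "avoidance"), center = TRUE,
                     dfMethod = "normal"),
        io = list(ratings = NULL)
    )
}

pcCheckKeys <- function(given, allowed, where) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown)) {
        hint <- vapply(unknown, function(k) {
            cand <- allowed[agrepl(k, allowed, max.distance = 0.4)]
            if (length(cand)) sprintf(" (did you mean '%s'?)", cand[1]) else ""
        }, "")
        stop(sprintf("unknown key(s) in %s: %s", where,
                     paste0("'", unknown, "'", hint, collapse = ", ")))
    }
}

#' Validate and default-fill a pipeline configuration
#'
#' Accepts a YAML file path or a nested list.  Unknown keys are rejected
#' (with a nearest-key suggestion); missing keys receive documented
#' defaults; band ranges, percentile, pooling mode and predictor names are
#' checked.  The returned object is an idempotent, fully defaulted
#' `pcRunConfig`.
#'
#' @param config YAML path, nested list, or an already validated
#'   `pcRunConfig`.
#' @return a `pcRunConfig` list.
#' @export
validateConfig <- function(config = list()) {
    if (inherits(config, "pcRunConfig")) return(config)
    if (is.character(config)) {
        if (!file.exists(config))
            stop(sprintf("config file not found: %s", config))
        config <- yaml::read_yaml(config)
        if (is.null(config)) config <- list()
    }
    def <- pcDefaultConfig()
    pcCheckKeys(config, names(def), "config")
    out <- def
    out$seed <- if (!is.null(config$seed)) as.integer(config$seed) else def$seed
    for (blk in c("simulate", "spectral", "mask", "model", "io")) {
        if (!is.null(config[[blk]])) {
            pcCheckKeys(config[[blk]], names(def[[blk]]), blk)
            out[[blk]] <- utils::modifyList(def[[blk]], config[[blk]])
        }
    }
    if (!is.null(config$bands))
        out$bands <- lapply(config$bands, as.numeric)
    # type/range checks (constructors carry the detailed validation)
    do.call(bandSet, out$bands)
    if (out$mask$q <= 0 || out$mask$q > 100)
        stop("mask.q must be in (0, 100]")
    if (!out$mask$pooling %in% c("individual", "group"))
        stop("mask.pooling must be 'individual' or 'group'")
    if (!all(out$model$predictors %in% c("anxiety", "avoidance")))
        stop("model.predictors must be a subset of anxiety, avoidance")
    if (!out$model$dfMethod %in% c("normal", "residual"))
        stop("model.dfMethod must be 'normal' or 'residual'")
    if (out$simulate$trialsPerCondition < 2)
        stop("simulate.trialsPerCondition must be >= 2")
    if (out$spectral$windowStart >= out$spectral$windowEnd)
        stop("spectral.windowStart must be < windowEnd")
    if (is.character(out$simulate$montage) &&
        !out$simulate$montage %in% c("default", "reduced"))
        stop("simulate.montage must be 'default', 'reduced', or a montage spec list")
    structure(out, class = "pcRunConfig")
}

#' @export
print.pcRunConfig <- function(x, ...) {
    cat("pcRunConfig:\n")
    cat(sprintf("  seed %d; %d participants, %d trials/condition @ %g Hz\n",
                x$seed, x$simulate$nParticipants,
                x$simulate$trialsPerCondition, x$simulate$srate))
    cat(sprintf("  bands: %s\n",
                paste(sprintf("%s %g-%g", names(x$bands),
                              vapply(x$bands, `[`, 0, 1),
                              vapply(x$bands, `[`, 0, 2)), collapse = ", ")))
    cat(sprintf("  mask: q = %g, pooling %s, baseline %s\n",
                x$mask$q, x$mask$pooling, x$mask$baseline))
    invisible(x)
}

#' Demonstration configuration
#'
#' A small two-band (theta, beta) configuration — 12 participants on the
#' reduced 12-channel montage, 10 trials per condition at 250 Hz — that
#' runs the full pipeline in seconds while planting the demonstration
#' ground truth of [defaultCouplingEdges()]: a negative Reappraise x
#' anxiety theta effect and a positive Suppress x avoidance beta effect.
#'
#' @param seed master seed.
#' @return a `pcRunConfig`.
#' @export
demoConfig <- function(seed = 42L) {
    validateConfig(list(
        seed = as.integer(seed),
        simulate = list(nParticipants = 12L, trialsPerCondition = 10L,
                        srate = 250, montage = "reduced"),
        bands = list(theta = c(4, 8), beta = c(15, 30))))
}

pcConfigHash <- function(config) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
    unname(tools::md5sum(tmp))
}

pcBuildMontage <- function(spec) {
    if (is.character(spec)) {
        return(switch(spec, default = defaultMontage(),
                      reduced = reducedMontage(),
                      stop(sprintf("unknown montage '%s'", spec))))
    }
    montage(spec$labels, roiMap = spec[setdiff(names(spec), "labels")])
}

pcBuildEdges <- function(spec, mont, bandNames = NULL) {
    if (is.character(spec)) {
        return(switch(spec,
                      default = {
                          e <- defaultCouplingEdges(mont)
                          if (is.null(bandNames)) e
                          else Filter(function(x) x@band %in% bandNames, e)
                      },
                      none = list(),
                      stop(sprintf("unknown edges spec '%s'", spec))))
    }
    lapply(spec, function(e)
        couplingEdge(pair = unlist(e$pair), band = e$band,
                     baseLag = if (is.null(e$baseLag)) pi / 2 else e$baseLag,
                     intercept = if (is.null(e$intercept)) 0 else e$intercept,
                     offsets = unlist(e$offsets), slopes = unlist(e$slopes),
                     dimension = if (is.null(e$dimension)) "anxiety" else e$dimension,
                     conditions = c("NatNeutral", "NatNegative", "Reappraise",
                                    "Suppress")))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> window -> multitaper -> debiased-wPLI ->
#' baseline contrasts -> percentile mask -> ROI metrics -> mixed-effects
#' moderation models (with per-predictor BH-FDR), persisting intermediate
#' TSV/CSV artifacts and a deterministic JSON report.  Stage timings go to
#' `runlog.jsonl`; the report JSON contains no timestamps, so reruns with
#' the same configuration are byte-identical.
#'
#' @param config a `pcRunConfig`, nested list, or YAML path
#'   (see [validateConfig()]).
#' @param outDir output directory.
#' @param resume reuse per-participant connectivity TSVs already present in
#'   `outDir/conn` (matched by config hash) instead of re-simulating.
#' @param verbose emit progress messages.
#' @return a `pcRunReport` list: thresholds, pair counts, ROI metric
#'   summaries, model tables, fit criteria, effects with FDR, optional
#'   behavioural statistics, config hash and package version.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("pcrun"),
                        resume = FALSE, verbose = TRUE) {
    config <- validateConfig(config)
    hash <- pcConfigHash(config)
    connDir <- file.path(outDir, "conn", hash)
    dir.create(connDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(outDir, "runlog.jsonl")
    t00 <- proc.time()[3]
    logStage <- function(stage, t0, extra = list()) {
        rec <- c(list(stage = stage, seconds = round(proc.time()[3] - t0, 3)),
                 extra)
        cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
            file = logPath, append = TRUE)
        if (verbose)
            message(sprintf("[%s] %.2fs", stage, proc.time()[3] - t0))
    }

    mont <- pcBuildMontage(config$simulate$montage)
    edges <- pcBuildEdges(config$simulate$edges, mont, names(config$bands))
    bands <- do.call(bandSet, config$bands)
    nch <- length(chanLabels(mont))
    sim <- config$simulate
    mixing <- NULL
    if (sim$mixingLeakage > 0) {
        set.seed(pcParticipantSeed(config$seed, 999983L))
        mixing <- randomMixing(nch, sim$mixingLeakage)
    }
    design <- designSpec(trialsPerCondition = sim$trialsPerCondition,
                         srate = sim$srate, t0 = sim$t0,
                         duration = sim$duration, snr = sim$snr,
                         mixing = mixing, dropout = sim$dropout,
                         bands = bands)

    t0 <- proc.time()[3]
    cohort <- sampleCohort(sim$nParticipants,
                           anxietyMean = sim$anxietyMean,
                           anxietySd = sim$anxietySd,
                           avoidanceMean = sim$avoidanceMean,
                           avoidanceSd = sim$avoidanceSd,
                           correlation = sim$correlation,
                           seed = config$seed)
    utils::write.csv(cohort, file.path(outDir, "participants.csv"),
                     row.names = FALSE)
    logStage("cohort", t0)

    freqRange <- range(unlist(config$bands))
    t0 <- proc.time()[3]
    conn <- list()
    for (i in seq_len(nrow(cohort))) {
        id <- cohort$id[i]
        paths <- outer(design$conditions, bandNames(bands),
                       function(co, bn) file.path(connDir,
                                                  sprintf("%s_%s_%s.tsv", id, co, bn)))
        if (resume && all(file.exists(paths))) {
            for (p in paths) conn[[basename(p)]] <- readConnMatrix(p)
            next
        }
        eps <- simulateParticipant(cohort[i, ], edges, design, mont,
                                   seed = config$seed, index = i)
        for (e in eps) {
            if (isTRUE(sim$writeEpochs)) {
                edir <- file.path(outDir, "epochs")
                dir.create(edir, showWarnings = FALSE)
                writeEDF(e, file.path(edir, sprintf("%s_%s.edf",
                                                    e@participant, e@condition)))
            }
            w <- selectWindow(e, config$spectral$windowStart,
                              config$spectral$windowEnd)
            co <- multitaperCoeffs(w, config$spectral$halfBandwidth, freqRange)
            cms <- bandConnectivity(co, bands)
            for (cm in cms) {
                fn <- sprintf("%s_%s_%s.tsv", cm@participant, cm@condition,
                              cm@band)
                writeConnMatrix(cm, file.path(connDir, fn))
                conn[[fn]] <- cm
            }
        }
    }
    logStage("connectivity", t0, list(matrices = length(conn)))

    t0 <- proc.time()[3]
    deltas <- deltaMatrices(conn, baseline = config$mask$baseline)
    groups <- groupDelta(deltas)
    poolSet <- if (config$mask$pooling == "individual") deltas else groups
    thresholds <- positivePercentileThreshold(poolSet, q = config$mask$q)
    masks <- lapply(groups, function(g)
        applyMask(g, thresholds[[g@band]], q = config$mask$q,
                  pooling = config$mask$pooling))
    maskDir <- file.path(outDir, "mask")
    dir.create(maskDir, showWarnings = FALSE)
    pairCounts <- do.call(rbind, lapply(masks, function(mk) {
        utils::write.csv(pairList(mk),
                         file.path(maskDir, sprintf("pairs_%s_%s.csv",
                                                    mk@band, mk@condition)),
                         row.names = FALSE)
        data.frame(band = mk@band, condition = mk@condition,
                   threshold = mk@threshold, nPairs = nrow(pairList(mk)),
                   stringsAsFactors = FALSE)
    }))
    rownames(pairCounts) <- NULL
    logStage("mask", t0)

    t0 <- proc.time()[3]
    deltaBands <- vapply(deltas, band, "")
    modelTable <- NULL
    for (bn in bandNames(bands)) {
        bandMasks <- Filter(function(mk) mk@band == bn, masks)
        uni <- maskUnion(bandMasks)
        if (!nrow(uni)) {
            if (verbose)
                message(sprintf("band %s: no suprathreshold pairs; skipped", bn))
            next
        }
        met <- suppressWarnings(
            roiMetrics(deltas[deltaBands == bn], uni, mont))
        modelTable <- rbind(modelTable, buildModelTable(met, cohort))
    }
    if (!is.null(modelTable))
        utils::write.csv(modelTable, file.path(outDir, "model_table.csv"),
                         row.names = FALSE)
    logStage("roi_metrics", t0)

    t0 <- proc.time()[3]
    effects <- NULL
    criteria <- NULL
    if (!is.null(modelTable)) {
        for (pred in config$model$predictors) {
            for (bn in unique(modelTable$band)) {
                for (roi in unique(modelTable$roi)) {
                    sub <- modelTable[modelTable$band == bn &
                                      modelTable$roi == roi, ]
                    if (all(is.na(sub$dwpli))) next
                    fit <- fitLmm(sub, predictor = pred,
                                  center = config$model$center,
                                  dfMethod = config$model$dfMethod)
                    fx <- fixedEffects(fit)
                    effects <- rbind(effects, data.frame(
                        predictor = pred, roi = roi, band = bn,
                        effect = fx$label, estimate = fx$estimate,
                        se = fx$se, p = fx$p, stringsAsFactors = FALSE))
                    criteria <- rbind(criteria, data.frame(
                        predictor = pred, roi = roi, band = bn,
                        aic = fit@aic, bic = fit@bic, logLik = fit@logLik,
                        deviance = fit@deviance, ranVar = fit@ranVar,
                        resVar = fit@resVar, stringsAsFactors = FALSE))
                }
            }
        }
        if (!is.null(effects)) {
            effects$fdr <- NA_real_
            for (pred in unique(effects$predictor)) {
                fam <- which(effects$predictor == pred &
                             effects$effect != "Intercept")
                effects$fdr[fam] <- bhFdr(effects$p[fam])
            }
        }
    }
    logStage("lmm", t0)

    behavioural <- NULL
    if (!is.null(config$io$ratings)) {
        t0 <- proc.time()[3]
        behavioural <- behaviouralStats(config$io$ratings)
        logStage("behavioural", t0)
    }

    report <- structure(list(
        package = "phaseConn",
        version = as.character(utils::packageVersion("phaseConn")),
        configHash = hash, seed = config$seed,
        nParticipants = nrow(cohort),
        thresholds = as.list(thresholds),
        pairCounts = pairCounts,
        effects = effects, fitCriteria = criteria,
        behavioural = behavioural), class = "pcRunReport")
    jsonlite::write_json(unclass(report), file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    renderReport(report, outDir)
    logStage("total", t00)
    report
}

#' Behavioural statistics for arousal ratings
#'
#' Reads a trial-level ratings CSV (columns `participant`, `condition`,
#' `rating`), averages ratings per participant x condition, gates each
#' condition with Shapiro-Wilk, and runs the Friedman test with Dunn's
#' post-hoc comparisons and paired Cohen's d per condition pair.
#'
#' @param ratingsCsv path to the ratings CSV.
#' @return list with `means`, `shapiro`, `friedman`, `dunn`.
#' @export
behaviouralStats <- function(ratingsCsv) {
    d <- utils::read.csv(ratingsCsv, stringsAsFactors = FALSE)
    for (col in c("participant", "condition", "rating"))
        if (!col %in% names(d))
            stop(sprintf("ratings CSV is missing column '%s'", col))
    wide <- tapply(d$rating, list(d$participant, d$condition), mean)
    if (anyNA(wide))
        stop("ratings are incomplete: every participant needs every condition")
    shap <- lapply(colnames(wide), function(cn) {
        g <- shapiroWilkGate(wide[, cn])
        data.frame(condition = cn, W = g$W, p = g$p.value,
                   useNonparametric = g$useNonparametric)
    })
    shap <- do.call(rbind, shap)
    fr <- friedmanTest(wide)
    du <- dunnPosthoc(wide)
    du$cohensD <- apply(du, 1, function(r)
        cohensDPaired(wide[, r[["group1"]]], wide[, r[["group2"]]]))
    list(means = data.frame(condition = colnames(wide),
                            mean = colMeans(wide),
                            sd = apply(wide, 2, stats::sd)),
         shapiro = shap,
         friedman = fr,
         dunn = du)
}

#' Render report tables
#'
#' Produces the summary tables: the full fixed-effects table, the
#' significant-effects table in the conventional
#' (Predictor, ROI, Band, Effect, Estimate, P, FDR) layout, and the
#' per-band suprathreshold pair counts.  Column order is fixed as listed.
#'
#' @param report a `pcRunReport` from [runPipeline()].
#' @param outDir optional directory; when given, writes `effects.csv`,
#'   `significant.csv` and `paircounts.csv`.
#' @return named list of data.frames, invisibly when writing.
#' @export
renderReport <- function(report, outDir = NULL) {
    eff <- report$effects
    sig <- data.frame(Predictor = character(0), ROI = character(0),
                      Band = character(0), Effect = character(0),
                      Estimate = numeric(0), P = numeric(0),
                      FDR = numeric(0), stringsAsFactors = FALSE)
    full <- sig
    if (!is.null(eff) && nrow(eff)) {
        full <- data.frame(
            Predictor = ifelse(eff$predictor == "anxiety",
                               "Attachment anxiety", "Attachment avoidance"),
            ROI = eff$roi, Band = eff$band, Effect = eff$effect,
            Estimate = eff$estimate, P = eff$p, FDR = eff$fdr,
            stringsAsFactors = FALSE)
        keep <- !is.na(full$FDR) & full$FDR < 0.05
        sig <- full[keep, , drop = FALSE]
        rownames(sig) <- NULL
    }
    tables <- list(effects = full, significant = sig,
                   pairCounts = report$pairCounts)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(tables$effects, file.path(outDir, "effects.csv"),
                         row.names = FALSE)
        utils::write.csv(tables$significant,
                         file.path(outDir, "significant.csv"),
                         row.names = FALSE)
        utils::write.csv(tables$pairCounts,
                         file.path(outDir, "paircounts.csv"),
                         row.names = FALSE)
        return(invisible(tables))
    }
    tables
}

#' @export
print.pcRunReport <- function(x, ...) {
    cat(sprintf("pcRunReport (%s %s, config %s, seed %d)\n", x$package,
                x$version, substr(x$configHash, 1, 8), x$seed))
    cat("Thresholds:\n")
    for (bn in names(x$thresholds))
        cat(sprintf("  %-6s %.4g\n", bn, x$thresholds[[bn]]))
    cat("Suprathreshold pair counts:\n")
    print(x$pairCounts, row.names = FALSE)
    if (!is.null(x$effects)) {
        sig <- x$effects[!is.na(x$effects$fdr) & x$effects$fdr < 0.05, ]
        cat(sprintf("Significant effects after FDR: %d\n", nrow(sig)))
        if (nrow(sig)) print(sig, row.names = FALSE, digits = 3)
    }
    invisible(x)
}
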