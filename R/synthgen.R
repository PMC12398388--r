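#' Sample a synthetic cohort with attachment scores
#'
#' Draws per-participant attachment anxiety and avoidance scores from a
#' (optionally correlated) bivariate normal truncated to the 1-7 Likert
#' range of the ECR-12 item-mean scale.  Sampling is by rejection, so the
#' truncation is exact.  A zero SD yields the degenerate distribution at the
#' mean.
#'
#' @param nParticipants number of participants (>= 2).
#' @param anxietyMean,anxietySd,avoidanceMean,avoidanceSd moments of the
#'   untruncated normals; SDs must be >= 0 and means inside \[1, 7\].
#' @param correlation correlation between the two latent normals (default 0).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return data.frame with columns `id`, `anxiety`, `avoidance`;
#'   all scores in \[1, 7\].
#' @examples
#' head(sampleCohort(6, seed = 7))
#' @export
sampleCohort <- function(nParticipants,
                         anxietyMean = 3.5, anxietySd = 1.2,
                         avoidanceMean = 3.5, avoidanceSd = 1.2,
                         correlation = 0, seed = 1L) {
    if (nParticipants < 2L)
        stop("nParticipants must be >= 2")
    if (anxietySd < 0 || avoidanceSd < 0)
        stop("SDs must be >= 0")
    if (anxietyMean < 1 || anxietyMean > 7 || avoidanceMean < 1 || avoidanceMean > 7)
        stop("means must lie in [1, 7]")
    if (abs(correlation) >= 1)
        stop("correlation must lie in (-1, 1)")
    set.seed(as.integer(seed))
    n <- as.integer(nParticipants)
    anx <- numeric(n); avd <- numeric(n)
    filled <- 0L
    while (filled < n) {
        m <- max(2L * (n - filled), 16L)
        z1 <- stats::rnorm(m)
        z2 <- correlation * z1 + sqrt(1 - correlation^2) * stats::rnorm(m)
        a <- anxietyMean + anxietySd * z1
        b <- avoidanceMean + avoidanceSd * z2
        ok <- a >= 1 & a <= 7 & b >= 1 & b <= 7
        take <- min(sum(ok), n - filled)
        if (take > 0L) {
            idx <- which(ok)[seq_len(take)]
            anx[filled + seq_len(take)] <- a[idx]
            avd[filled + seq_len(take)] <- b[idx]
            filled <- filled + take
        }
    }
    data.frame(id = sprintf("P%02d", seq_len(n)),
               anxiety = anx, avoidance = avd,
               stringsAsFactors = FALSE)
}

#' Construct a coupling edge
#'
#' @param pair character(2): the two coupled channel labels.
#' @param band name of the band the shared oscillation frequency is drawn
#'   from (uniformly within the band's range).
#' @param baseLag base phase lag in radians (not 0 or pi).
#' @param intercept logistic-scale intercept of the strength model.
#' @param offsets named numeric, per-condition logistic offsets.  The names
#'   of `offsets` (after merging with `slopes` and `conditions`) define the
#'   conditions known to this edge.
#' @param slopes named numeric, per-condition slopes on the centred
#'   attachment score.
#' @param dimension which attachment dimension the slopes act on
#'   ("anxiety" or "avoidance").
#' @param amplitude oscillation amplitude in microvolts.
#' @param jitterMap function kappa -> circular jitter SD in radians;
#'   must be non-increasing with `jitterMap(1) == 0` for a perfectly
#'   consistent lag at kappa = 1.  Default `pi * (1 - kappa)`.
#' @param conditions optional character vector of additional known
#'   conditions (offset and slope 0).  Defaults to the standard four-task
#'   design when no condition is named anywhere.
#' @return a [CouplingEdge].
#' @examples
#' couplingEdge(c("Fz", "Pz"), "theta", offsets = c(Reappraise = 2))
#' @export
couplingEdge <- function(pair, band, baseLag = pi / 2, intercept = 0,
                         offsets = numeric(), slopes = numeric(),
                         dimension = "anxiety", amplitude = 1,
                         jitterMap = function(kappa) pi * (1 - kappa),
                         conditions = NULL) {
    known <- unique(c(names(offsets), names(slopes), conditions))
    if (!length(known))
        known <- c("NatNeutral", "NatNegative", "Reappraise", "Suppress")
    off <- structure(numeric(length(known)), names = known)
    off[names(offsets)] <- offsets
    slo <- structure(numeric(length(known)), names = known)
    slo[names(slopes)] <- slopes
    new("CouplingEdge", pair = as.character(pair), band = band,
        baseLag = baseLag, intercept = intercept, offsets = off,
        slopes = slo, dimension = dimension, amplitude = amplitude,
        jitterMap = jitterMap)
}

#' Coupling strength for a condition and participant
#'
#' Deterministic logistic strength model:
#' `kappa = plogis(intercept + offsets[condition] +
#' slopes[condition] * (score - center))` where `score` is the
#' participant's attachment score on the edge's dimension and `center`
#' fixes the centring of the 1-7 scale (default: scale midpoint 4, so the
#' strength model does not depend on the cohort it is embedded in).
#'
#' @param edge a [CouplingEdge].
#' @param condition condition label; must be known to the edge.
#' @param participant list or one-row data.frame with `anxiety` and
#'   `avoidance` entries.
#' @param center centring constant for the attachment score.
#' @return kappa in \[0, 1\].
#' @examples
#' e <- couplingEdge(c("Fz", "Pz"), "theta",
#'                   offsets = c(Reappraise = 1),
#'                   slopes = c(Reappraise = -0.5))
#' couplingStrength(e, "Reappraise", list(anxiety = 6, avoidance = 4))
#' @export
couplingStrength <- function(edge, condition, participant, center = 4) {
    stopifnot(is(edge, "CouplingEdge"))
    if (!condition %in% names(edge@offsets))
        stop(sprintf("condition '%s' unknown to edge %s-%s (known: %s)",
                     condition, edge@pair[1], edge@pair[2],
                     paste(names(edge@offsets), collapse = ", ")))
    score <- participant[[edge@dimension]]
    if (is.null(score) || !is.finite(score))
        stop(sprintf("participant lacks a finite '%s' score", edge@dimension))
    stats::plogis(edge@intercept + edge@offsets[[condition]] +
                  edge@slopes[[condition]] * (score - center))
}

#' Simulation design parameters
#'
#' Bundles the per-trial design of the synthetic cohort: trial counts,
#' sampling rate, epoch span, signal-to-noise ratio, condition set, bands
#' and the instantaneous mixing matrix (volume-conduction surrogate).
#'
#' The study-design defaults are 15 trials per condition (optionally
#' dropped out uniformly to 8-15 to emulate artifact rejection), 500 Hz,
#' epochs spanning -1.0..4.0 s, and the four standard conditions.
#'
#' @param trialsPerCondition trials per condition (>= 2; the study design
#'   uses 8-15).
#' @param srate sampling rate in Hz.
#' @param t0 epoch start (s, relative to stimulus onset).
#' @param duration epoch length in seconds.
#' @param snr ratio of per-edge oscillation RMS to background-noise RMS;
#'   `Inf` disables noise.
#' @param conditions condition labels simulated.
#' @param mixing channels x channels real mixing matrix, or `NULL` for
#'   identity (no leakage).
#' @param dropout if `TRUE`, per participant x condition trial counts are
#'   drawn uniformly from 8..`trialsPerCondition`.
#' @param bands a [BandSet] defining the edge bands.
#' @return a list of class `pcDesign`.
#' @export
designSpec <- function(trialsPerCondition = 15L, srate = 500, t0 = -1.0,
                       duration = 5.0, snr = 1,
                       conditions = c("NatNeutral", "NatNegative",
                                      "Reappraise", "Suppress"),
                       mixing = NULL, dropout = FALSE,
                       bands = defaultBands()) {
    if (trialsPerCondition < 2L)
        stop("trialsPerCondition must be >= 2")
    if (!is.null(mixing)) {
        mixing <- as.matrix(mixing)
        if (nrow(mixing) != ncol(mixing))
            stop("mixing matrix must be square")
        if (!is.numeric(mixing) || !all(is.finite(mixing)))
            stop("mixing matrix must be real and finite")
    }
    structure(list(trialsPerCondition = as.integer(trialsPerCondition),
                   srate = srate, t0 = t0, duration = duration, snr = snr,
                   conditions = conditions, mixing = mixing,
                   dropout = isTRUE(dropout), bands = bands),
              class = "pcDesign")
}

#' Spectrally shaped 1/f noise
#'
#' White Gaussian noise shaped in the frequency domain to a 1/f power
#' spectrum (amplitude 1/sqrt(f), DC removed), rescaled to unit standard
#' deviation.  Consumes `n` normal variates from the current RNG stream.
#'
#' @param n number of samples.
#' @param srate sampling rate in Hz.
#' @param exponent spectral exponent of the power spectrum (default 1).
#' @return numeric vector of length `n`, SD 1.
#' @export
oneOverFNoise <- function(n, srate, exponent = 1) {
    as.vector(pcNoiseMatrix(n, 1L, srate, exponent))
}

# columns of independent unit-SD 1/f noise; one mvfft per call
pcNoiseMatrix <- function(n, ncols, srate, exponent = 1) {
    akey <- sprintf("famp_%d_%.12g_%g", n, srate, exponent)
    amp <- .pcCache[[akey]]
    if (is.null(amp)) {
        k <- 0:(n - 1)
        f <- pmin(k, n - k) * srate / n
        amp <- c(0, f[-1]^(-exponent / 2))
        .pcCache[[akey]] <- amp
    }
    w <- matrix(stats::rnorm(n * ncols), n, ncols)
    x <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE)) / n
    s <- sqrt(colMeans(x^2) - colMeans(x)^2) * sqrt(n / (n - 1))
    x / rep(pmax(s, .Machine$double.eps), each = n)
}

#' Random instantaneous mixing matrix
#'
#' `diag(n) + leakage * Z / sqrt(n)` with standard-normal `Z`: an identity
#' channel map plus dense zero-lag leakage, the volume-conduction surrogate.
#' Uses the current RNG stream.
#'
#' @param nChannels matrix dimension.
#' @param leakage leakage strength; 0 gives the identity.
#' @return nChannels x nChannels numeric matrix.
#' @export
randomMixing <- function(nChannels, leakage = 0.1) {
    diag(nChannels) +
        leakage * matrix(stats::rnorm(nChannels^2), nChannels) / sqrt(nChannels)
}

pcParticipantSeed <- function(seed, index) {
    as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

#' Simulate epochs for one participant
#'
#' Per trial, each coupled edge contributes a band-limited sinusoid (one
#' frequency drawn uniformly within the edge's band, a uniform random trial
#' phase) to both of its channels; the second channel is phase-shifted by
#' the edge's base lag plus a circular jitter drawn from a wrapped normal
#' whose SD decreases with the coupling strength kappa.  Independent 1/f
#' background noise is added per channel, and the real mixing matrix is
#' applied after source placement (zero-lag leakage).  The participant's
#' random stream is derived from the master seed by a fixed offset, so
#' cohort size changes never reshuffle earlier participants.
#'
#' @param spec one-row data.frame or list with `id`, `anxiety`, `avoidance`.
#' @param edges list of [CouplingEdge].
#' @param design a [designSpec()].
#' @param montage a [Montage].
#' @param seed master integer seed.
#' @param index participant index used for the fixed seed offset.
#' @return named list of [EpochedEEG], one per condition.
#' @export
simulateParticipant <- function(spec, edges, design = designSpec(),
                                montage = defaultMontage(), seed = 1L,
                                index = 1L) {
    labels <- chanLabels(montage)
    nch <- length(labels)
    mixing <- design$mixing
    if (is.null(mixing)) mixing <- diag(nch)
    if (nrow(mixing) != nch)
        stop(sprintf("mixing matrix is %dx%d but montage has %d channels",
                     nrow(mixing), ncol(mixing), nch))
    ranges <- bandRanges(design$bands)
    for (e in edges) {
        bad <- setdiff(e@pair, labels)
        if (length(bad))
            stop(sprintf("edge channel label(s) not in montage: %s",
                         paste(bad, collapse = ", ")))
        if (!e@band %in% names(ranges))
            stop(sprintf("edge band '%s' not in the design's band set", e@band))
    }
    set.seed(pcParticipantSeed(seed, index))
    n <- round(design$duration * design$srate)
    tt <- design$t0 + (0:(n - 1)) / design$srate
    noiseSd <- if (is.infinite(design$snr)) 0 else 1 / (sqrt(2) * design$snr)
    out <- list()
    for (cond in design$conditions) {
        ntr <- design$trialsPerCondition
        if (design$dropout)
            ntr <- sample(8:design$trialsPerCondition, 1L)
        # per-trial edge draws first, then one noise block: the stream layout
        # is fixed per condition, independent of how channels are assembled
        draws <- vector("list", length(edges))
        for (j in seq_along(edges)) {
            e <- edges[[j]]
            kap <- couplingStrength(e, cond, spec)
            sdj <- e@jitterMap(kap)
            draws[[j]] <- list(
                ia = match(e@pair[1], labels), ib = match(e@pair[2], labels),
                f = stats::runif(ntr, ranges[[e@band]][1], ranges[[e@band]][2]),
                ph = stats::runif(ntr, 0, 2 * pi),
                jit = if (sdj > 0) stats::rnorm(ntr, 0, sdj) else numeric(ntr))
        }
        S <- array(0, dim = c(n, nch, ntr))           # samples x channels x trials
        if (noiseSd > 0)
            S[] <- noiseSd * pcNoiseMatrix(n, nch * ntr, design$srate)
        for (j in seq_along(edges)) {
            e <- edges[[j]]; dr <- draws[[j]]
            for (tr in seq_len(ntr)) {
                w <- 2 * pi * dr$f[tr] * tt + dr$ph[tr]
                S[, dr$ia, tr] <- S[, dr$ia, tr] + e@amplitude * sin(w)
                S[, dr$ib, tr] <- S[, dr$ib, tr] +
                    e@amplitude * sin(w - e@baseLag - dr$jit[tr])
            }
        }
        X <- matrix(aperm(S, c(2, 1, 3)), nrow = nch)  # channels x (samples*trials)
        dat <- aperm(array(mixing %*% X, dim = c(nch, n, ntr)), c(3, 1, 2))
        out[[cond]] <- new("EpochedEEG", participant = as.character(spec$id),
                           condition = cond, data = dat, srate = design$srate,
                           t0 = design$t0, montage = montage)
    }
    out
}

#' Simulate a full synthetic cohort
#'
#' Applies [simulateParticipant()] to every row of `cohort`.  Identical
#' `(cohort, edges, design, seed)` give bit-identical output.
#'
#' @param cohort data.frame from [sampleCohort()].
#' @param edges list of [CouplingEdge] (may be empty for pure-noise data).
#' @param design a [designSpec()].
#' @param montage a [Montage].
#' @param seed master integer seed.
#' @return named list `"<id>.<condition>"` of [EpochedEEG].
#' @examples
#' coh <- sampleCohort(2, seed = 1)
#' des <- designSpec(trialsPerCondition = 2, srate = 100, duration = 1,
#'                   t0 = 0, conditions = "NatNeutral")
#' ep <- simulateEpochs(coh, list(), des,
#'                      montage(c("Fz", "Pz"), list(frontal = "Fz")), seed = 1)
#' names(ep)
#' @export
simulateEpochs <- function(cohort, edges, design = designSpec(),
                           montage = defaultMontage(), seed = 1L) {
    out <- list()
    for (i in seq_len(nrow(cohort))) {
        eps <- simulateParticipant(cohort[i, ], edges, design, montage,
                                   seed = seed, index = i)
        names(eps) <- paste(cohort$id[i], names(eps), sep = ".")
        out <- c(out, eps)
    }
    out
}

#' Demonstration coupling edges
#'
#' Ground-truth edges mirroring the study's reported moderation pattern:
#' theta coupling between frontal and posterior sites that strengthens under
#' Reappraise and weakens with attachment anxiety, and beta coupling from
#' central sites that strengthens under Suppress and grows with attachment
#' avoidance.  Candidate pairs are filtered to the supplied montage.
#'
#' @param montage a [Montage].
#' @return list of [CouplingEdge] (two theta, two beta).
#' @export
defaultCouplingEdges <- function(montage = defaultMontage()) {
    labels <- chanLabels(montage)
    pick <- function(cands, k) {
        keep <- Filter(function(p) all(p %in% labels), cands)
        if (length(keep) < k)
            stop("montage does not contain enough candidate edge channels")
        keep[seq_len(k)]
    }
    thetaPairs <- pick(list(c("Fz", "Pz"), c("F3", "O1"), c("F4", "O2"),
                            c("F4", "Oz"), c("F3", "Pz")), 2)
    betaPairs <- pick(list(c("Cz", "Pz"), c("C3", "O1"), c("C4", "O2"),
                           c("C3", "Oz"), c("C4", "Pz")), 2)
    lags <- c(pi / 2, pi / 3)
    c(
        lapply(seq_along(thetaPairs), function(i)
            couplingEdge(thetaPairs[[i]], "theta", baseLag = lags[i],
                         intercept = -1,
                         offsets = c(Reappraise = 2),
                         slopes = c(Reappraise = -0.7),
                         dimension = "anxiety",
                         conditions = c("NatNeutral", "NatNegative", "Suppress"))),
        lapply(seq_along(betaPairs), function(i)
            couplingEdge(betaPairs[[i]], "beta", baseLag = lags[i],
                         intercept = -1,
                         offsets = c(Suppress = 1.5),
                         slopes = c(Suppress = 0.7),
                         dimension = "avoidance",
                         conditions = c("NatNeutral", "NatNegative", "Reappraise")))
    )
}

#' @rdname accessors
#' @export
setMethod("participant", "EpochedEEG", function(object) object@participant)
#' @rdname accessors
#' @export
setMethod("condition", "EpochedEEG", function(object) object@condition)
#' @rdname accessors
#' @export
setMethod("srate", "EpochedEEG", function(object) object@srate)
#' @rdname accessors
#' @export
setMethod("startTime", "EpochedEEG", function(object) object@t0)
#' @rdname accessors
#' @export
setMethod("epochData", "EpochedEEG", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("nTrials", "EpochedEEG", function(object) dim(object@data)[1])
#' @rdname accessors
#' @export
setMethod("chanLabels", "EpochedEEG", function(object) object@montage@labels)
#' @rdname accessors
#' @export
setMethod("roiMap", "EpochedEEG", function(object) object@montage@roiMap)

setMethod("show", "EpochedEEG", function(object) {
    d <- dim(object@data)
    cat(sprintf("EpochedEEG %s / %s: %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
                object@participant, object@condition, d[1], d[2], d[3],
                object@srate, object@t0))
})

setMethod("show", "CouplingEdge", function(object) {
    cat(sprintf("CouplingEdge %s-%s [%s], lag %.3f rad, dim %s\n",
                object@pair[1], object@pair[2], object@band, object@baseLag,
                object@dimension))
    cat(sprintf("  logit(kappa) = %.2f + offset + slope * centred %s\n",
                object@intercept, object@dimension))
})
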