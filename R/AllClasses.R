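#' @import methods
NULL

#' Montage: ordered channel labels with named regions of interest
#'
#' A scalp montage is an ordered set of unique channel labels (10/20
#' nomenclature) together with a named list of regions of interest (ROIs),
#' each ROI being a subset of the labels.  The default 30-channel montage is
#' returned by [defaultMontage()].
#'
#' @slot labels character vector of unique channel names.
#' @slot roiMap named list of character vectors; every entry must be a
#'   subset of `labels`.
#'
#' @seealso [defaultMontage()], [roiLabels()]
#' @export
setClass("Montage", slots = c(labels = "character", roiMap = "list"))

setValidity("Montage", function(object) {
    msg <- NULL
    if (anyDuplicated(object@labels))
        msg <- c(msg, "channel labels must be unique")
    if (length(object@roiMap) && is.null(names(object@roiMap)))
        msg <- c(msg, "roiMap must be a named list")
    for (nm in names(object@roiMap)) {
        extra <- setdiff(object@roiMap[[nm]], object@labels)
        if (length(extra))
            msg <- c(msg, sprintf("ROI '%s' contains labels not in the montage: %s",
                                  nm, paste(extra, collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' BandSet: named frequency bands
#'
#' Named inclusive frequency ranges in Hz.  The defaults follow the
#' conventional emotion-regulation EEG analysis bands: delta 1-3, theta 4-8,
#' alpha 9-12, beta 15-30 Hz.
#'
#' @slot bands named list of length-2 numeric vectors `c(low, high)` in Hz.
#' @seealso [bandSet()], [defaultBands()]
#' @export
setClass("BandSet", slots = c(bands = "list"))

setValidity("BandSet", function(object) {
    b <- object@bands
    if (!length(b) || is.null(names(b)) || any(names(b) == ""))
        return("bands must be a non-empty named list")
    for (nm in names(b)) {
        r <- b[[nm]]
        if (!is.numeric(r) || length(r) != 2L || !all(is.finite(r)))
            return(sprintf("band '%s' must be a finite numeric range c(low, high)", nm))
        if (r[1] >= r[2])
            return(sprintf("band '%s' has low >= high (%g >= %g)", nm, r[1], r[2]))
    }
    rr <- do.call(rbind, b)
    o <- order(rr[, 1])
    rr <- rr[o, , drop = FALSE]
    if (nrow(rr) > 1L && any(rr[-1L, 1L] <= rr[-nrow(rr), 2L] - 1e-12 &
                             rr[-1L, 1L] < rr[-nrow(rr), 2L]))
        return("bands must not overlap")
    TRUE
})

#' CouplingEdge: ground-truth phase coupling between two channels
#'
#' Describes one coupled channel pair used by the synthetic generator: the
#' frequency band the shared oscillation is drawn from, the non-zero base
#' phase lag between the two channels, and a logistic strength model
#' producing a coupling strength kappa in \[0, 1\] from the experimental
#' condition and a participant's attachment score.  The jitter map converts
#' kappa into the standard deviation (radians) of the circular phase jitter
#' applied per trial; the default is `pi * (1 - kappa)`, so kappa = 1 gives
#' a perfectly constant lag and kappa = 0 a near-uniform phase.
#'
#' @slot pair character(2), distinct channel labels.
#' @slot band band name (must exist in the [BandSet] used at simulation).
#' @slot baseLag base phase offset in radians; must not be 0 or pi (modulo
#'   2*pi), otherwise the imaginary cross-spectrum would vanish.
#' @slot intercept,offsets,slopes logistic-scale strength model: kappa =
#'   plogis(intercept + offsets\[condition\] + slopes\[condition\] *
#'   centred attachment).  `offsets` and `slopes` are named by condition.
#' @slot dimension which attachment dimension drives `slopes`
#'   ("anxiety" or "avoidance").
#' @slot amplitude oscillation amplitude in microvolts.
#' @slot jitterMap function mapping kappa in \[0,1\] to jitter SD (radians).
#'
#' @seealso [couplingEdge()], [couplingStrength()], [simulateEpochs()]
#' @export
setClass("CouplingEdge", slots = c(
    pair = "character", band = "character", baseLag = "numeric",
    intercept = "numeric", offsets = "numeric", slopes = "numeric",
    dimension = "character", amplitude = "numeric", jitterMap = "function"))

setValidity("CouplingEdge", function(object) {
    msg <- NULL
    if (length(object@pair) != 2L || object@pair[1] == object@pair[2])
        msg <- c(msg, "pair must be two distinct channel labels")
    lag <- object@baseLag %% (2 * pi)
    if (min(abs(c(lag, lag - pi, lag - 2 * pi))) < 1e-8)
        msg <- c(msg, "baseLag must not be 0 or pi (imaginary cross-spectrum would vanish)")
    if (!object@dimension %in% c("anxiety", "avoidance"))
        msg <- c(msg, "dimension must be 'anxiety' or 'avoidance'")
    if (length(object@offsets) && is.null(names(object@offsets)))
        msg <- c(msg, "offsets must be named by condition")
    if (length(object@slopes) && is.null(names(object@slopes)))
        msg <- c(msg, "slopes must be named by condition")
    if (!is.finite(object@amplitude) || object@amplitude <= 0)
        msg <- c(msg, "amplitude must be positive")
    if (is.null(msg)) TRUE else msg
})

#' EpochedEEG: trial-resolved multichannel EEG for one participant/condition
#'
#' @slot participant participant identifier.
#' @slot condition condition label, one of "NatNeutral", "NatNegative",
#'   "Reappraise", "Suppress" for the standard design (other labels are
#'   permitted for generic use).
#' @slot data numeric array `trials x channels x samples` in microvolts.
#' @slot srate sampling rate in Hz (500 by default).
#' @slot t0 time of the first sample in seconds relative to stimulus onset
#'   (-1.0 by default; epochs span -1.0..4.0 s).
#' @slot montage the [Montage] the channel dimension is labelled by.
#'
#' @seealso [simulateEpochs()], [selectWindow()]
#' @export
setClass("EpochedEEG", slots = c(
    participant = "character", condition = "character", data = "array",
    srate = "numeric", t0 = "numeric", montage = "Montage"))

setValidity("EpochedEEG", function(object) {
    msg <- NULL
    d <- dim(object@data)
    if (length(d) != 3L)
        msg <- c(msg, "data must be a trials x channels x samples array")
    else {
        if (d[2] != length(object@montage@labels))
            msg <- c(msg, "channel dimension does not match montage labels")
        if (d[1] < 1L) msg <- c(msg, "at least one trial required")
    }
    if (!all(is.finite(object@data)))
        msg <- c(msg, "all samples must be finite")
    if (!is.finite(object@srate) || object@srate <= 0)
        msg <- c(msg, "srate must be positive")
    if (is.null(msg)) TRUE else msg
})

#' SpectralCoeffs: multitaper Fourier coefficients
#'
#' Complex DPSS-multitaper Fourier coefficients indexed by
#' `(trial, taper, channel, frequency bin)`.  Bin spacing is the reciprocal
#' of the analysis window length; tapers are unit-energy Slepian sequences.
#'
#' @slot participant,condition provenance labels.
#' @slot coeffs complex array `trial x taper x channel x bin`.
#' @slot freqs bin centre frequencies in Hz.
#' @slot nTapers number of DPSS tapers K.
#' @slot windowSpan analysis window length in seconds.
#' @slot srate sampling rate in Hz.
#' @slot labels channel labels for the channel dimension.
#'
#' @seealso [multitaperCoeffs()], [crossSpectra()]
#' @export
setClass("SpectralCoeffs", slots = c(
    participant = "character", condition = "character", coeffs = "array",
    freqs = "numeric", nTapers = "integer", windowSpan = "numeric",
    srate = "numeric", labels = "character"))

setValidity("SpectralCoeffs", function(object) {
    d <- dim(object@coeffs)
    msg <- NULL
    if (length(d) != 4L)
        msg <- c(msg, "coeffs must be trial x taper x channel x bin")
    else {
        if (d[2] != object@nTapers) msg <- c(msg, "taper dimension != nTapers")
        if (d[3] != length(object@labels)) msg <- c(msg, "channel dimension != labels")
        if (d[4] != length(object@freqs)) msg <- c(msg, "bin dimension != freqs")
    }
    if (object@nTapers < 1L) msg <- c(msg, "nTapers must be >= 1")
    if (!all(is.finite(Re(object@coeffs))) || !all(is.finite(Im(object@coeffs))))
        msg <- c(msg, "coefficients must be finite")
    if (is.null(msg)) TRUE else msg
})

#' CrossSpectra: per-pair, per-bin complex cross-spectral observations
#'
#' For each unordered channel pair and frequency bin, the pooled sequence of
#' per-(trial, taper) complex cross-spectral observations
#' `X = coeff(a) * Conj(coeff(b))`.  Observations are pooled with the trial
#' index varying fastest within each taper.
#'
#' @slot participant,condition provenance labels.
#' @slot obs complex array `observation x pair x bin`.
#' @slot pairs character matrix with columns `chanA`, `chanB`.
#' @slot freqs bin centre frequencies in Hz.
#' @slot labels channel labels of the source montage.
#'
#' @seealso [crossSpectra()], [bandConnectivity()]
#' @export
setClass("CrossSpectra", slots = c(
    participant = "character", condition = "character", obs = "array",
    pairs = "matrix", freqs = "numeric", labels = "character"))

setValidity("CrossSpectra", function(object) {
    d <- dim(object@obs)
    msg <- NULL
    if (length(d) != 3L)
        msg <- c(msg, "obs must be observation x pair x bin")
    else {
        if (d[2] != nrow(object@pairs)) msg <- c(msg, "pair dimension != pairs table")
        if (d[3] != length(object@freqs)) msg <- c(msg, "bin dimension != freqs")
    }
    if (ncol(object@pairs) != 2L) msg <- c(msg, "pairs must have two columns")
    if (is.null(msg)) TRUE else msg
})

#' ConnMatrix: band-wise debiased-wPLI connectivity matrix
#'
#' Symmetric channels x channels matrix of debiased weighted-Phase-Lag-Index
#' (squared-wPLI estimator) values for one participant, condition and band.
#' The diagonal is undefined (NA).  Off-diagonal values lie in \[-1, 1\]
#' (negative values are possible: the estimator is unbiased for squared wPLI
#' and is not clamped).  Entries whose estimator was undefined at every bin
#' (pure zero-lag) are NaN; `nUndefined` counts the NaN bin evaluations
#' encountered during band averaging.
#'
#' @slot participant,condition,band provenance labels.
#' @slot matrix symmetric numeric matrix with channel dimnames.
#' @slot nObs number of cross-spectral observations (trials x tapers).
#' @slot nUndefined count of undefined (NaN) per-bin estimates dropped from
#'   band averages.
#'
#' @seealso [bandConnectivity()], [debiasedWpli()]
#' @export
setClass("ConnMatrix", slots = c(
    participant = "character", condition = "character", band = "character",
    matrix = "matrix", nObs = "integer", nUndefined = "integer"))

setValidity("ConnMatrix", function(object) {
    m <- object@matrix
    msg <- NULL
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    off <- m[row(m) != col(m)]
    off <- off[is.finite(off)]
    if (length(off) && (min(off) < -1 - 1e-9 || max(off) > 1 + 1e-9))
        msg <- c(msg, "off-diagonal values must lie in [-1, 1]")
    if (!isTRUE(all.equal(m[lower.tri(m)], t(m)[lower.tri(m)])) &&
        !all(is.na(m[lower.tri(m)]) == is.na(t(m)[lower.tri(m)])))
        msg <- c(msg, "matrix must be symmetric")
    if (is.null(msg)) TRUE else msg
})

#' DeltaMatrix: condition-minus-baseline connectivity difference
#'
#' A [ConnMatrix] holding elementwise `condition - baseline` debiased-wPLI
#' differences for a participant (or, for group averages,
#' `participant = "group"`).
#'
#' @slot baseline the baseline condition label (usually "NatNeutral").
#' @seealso [deltaMatrices()], [groupDelta()]
#' @export
setClass("DeltaMatrix", contains = "ConnMatrix",
         slots = c(baseline = "character"))

#' MaskResult: data-driven threshold and suprathreshold pairs
#'
#' Result of thresholding a group-level [DeltaMatrix] at the q-th percentile
#' of pooled strictly-positive differences: the threshold, the deduplicated
#' list of suprathreshold unordered pairs, and the masked matrix
#' (subthreshold entries set to zero).
#'
#' @slot band,condition provenance labels.
#' @slot threshold the percentile threshold (delta-wPLI units, >= 0).
#' @slot q the percentile used (default 95).
#' @slot pairList data.frame with columns `chanA`, `chanB`, `delta`.
#' @slot maskedMatrix group delta matrix with entries <= threshold zeroed.
#' @slot pooling "individual" or "group" (which delta set the percentile
#'   pooled over).
#'
#' @seealso [applyMask()], [positivePercentileThreshold()]
#' @export
setClass("MaskResult", slots = c(
    band = "character", condition = "character", threshold = "numeric",
    q = "numeric", pairList = "data.frame", maskedMatrix = "matrix",
    pooling = "character"))

setValidity("MaskResult", function(object) {
    msg <- NULL
    if (object@threshold < 0) msg <- c(msg, "threshold must be >= 0")
    pl <- object@pairList
    if (!all(c("chanA", "chanB", "delta") %in% names(pl)))
        msg <- c(msg, "pairList must have columns chanA, chanB, delta")
    else if (nrow(pl)) {
        key <- paste(pmin(pl$chanA, pl$chanB), pmax(pl$chanA, pl$chanB))
        if (anyDuplicated(key)) msg <- c(msg, "pairList must be deduplicated")
        if (any(pl$delta <= object@threshold))
            msg <- c(msg, "every listed pair must exceed the threshold")
    }
    if (is.null(msg)) TRUE else msg
})

#' LMMResult: fitted linear mixed-effects moderation model
#'
#' Fixed-effect estimates (condition dummies, centred attachment, and their
#' interactions), random-intercept and residual variances, and
#' maximum-likelihood fit criteria for one band x ROI x attachment-predictor
#' model.
#'
#' @slot fixed data.frame with columns `term`, `label`, `estimate`, `se`,
#'   `stat`, `p`, `ciLow`, `ciHigh`.
#' @slot ranVar random-intercept variance (participant).
#' @slot resVar residual variance.
#' @slot aic,bic,logLik,deviance ML fit criteria (deviance = -2 logLik,
#'   AIC = -2 logLik + 2k for k fitted parameters).
#' @slot nObs,nGroups observations and participants used.
#' @slot nPar number of fitted parameters (fixed + variance components).
#' @slot band,roi,predictor provenance labels.
#' @slot terms character vector of fixed-effect term names (for nesting
#'   checks in likelihood-ratio tests).
#'
#' @seealso [fitLmm()], [likelihoodRatioTest()]
#' @export
setClass("LMMResult", slots = c(
    fixed = "data.frame", ranVar = "numeric", resVar = "numeric",
    aic = "numeric", bic = "numeric", logLik = "numeric", deviance = "numeric",
    nObs = "integer", nGroups = "integer", nPar = "integer",
    band = "character", roi = "character", predictor = "character",
    terms = "character"))

setValidity("LMMResult", function(object) {
    msg <- NULL
    if (object@ranVar < 0 || object@resVar < 0)
        msg <- c(msg, "variances must be >= 0")
    if (abs(object@deviance - (-2 * object@logLik)) > 1e-6)
        msg <- c(msg, "deviance must equal -2 logLik")
    if (abs(object@aic - (-2 * object@logLik + 2 * object@nPar)) > 1e-6)
        msg <- c(msg, "AIC must equal -2 logLik + 2 * nPar")
    if (is.null(msg)) TRUE else msg
})
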