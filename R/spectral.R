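.pcCache <- new.env(parent = emptyenv())

#' @rdname selectWindow
#' @export
setMethod("selectWindow", "EpochedEEG", function(epochs, tStart = 0.3, tEnd = 4.0) {
    d <- dim(epochs@data)
    ns <- d[3]
    eps <- 1e-9
    epochEnd <- epochs@t0 + ns / epochs@srate
    if (tStart >= tEnd)
        stop("tStart must be < tEnd")
    if (tStart < epochs@t0 - eps || tEnd > epochEnd + eps)
        stop(sprintf("window [%g, %g) outside epoch span [%g, %g]",
                     tStart, tEnd, epochs@t0, epochEnd))
    tt <- epochs@t0 + (0:(ns - 1)) / epochs@srate
    sel <- tt >= tStart - eps & tt < tEnd - eps
    if (!any(sel))
        stop("window contains no samples")
    out <- epochs
    out@data <- epochs@data[, , sel, drop = FALSE]
    out@t0 <- tt[which(sel)[1]]
    out
})

#' DPSS taper count for a smoothing half-bandwidth
#'
#' The convention `K = floor(2 * T * W) - 1` for window length `T` seconds
#' and half-bandwidth `W` Hz (the usual multitaper-FFT rule for spectral
#' smoothing of +-W).  The default analysis window (3.7 s, +-2 Hz) gives 13
#' tapers.
#'
#' @param windowLength window length in seconds.
#' @param halfBandwidth smoothing half-bandwidth in Hz.
#' @return integer taper count K >= 1.
#' @examples
#' dpssTaperCount(3.7, 2)  # 13
#' @export
dpssTaperCount <- function(windowLength, halfBandwidth) {
    if (windowLength <= 0) stop("windowLength must be positive")
    if (windowLength * halfBandwidth <= 1)
        stop(sprintf("time-bandwidth product %g <= 1: increase the window or the half-bandwidth",
                     windowLength * halfBandwidth))
    k <- floor(2 * windowLength * halfBandwidth + 1e-9) - 1
    as.integer(k)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem for the
#' time-bandwidth concentration problem; eigenvectors are unit-energy.
#' Results are cached per `(n, W, K)`.
#'
#' @param n taper length in samples.
#' @param W half-bandwidth as a fraction of the sampling rate
#'   (`halfBandwidth / srate`).
#' @param K number of tapers.
#' @return `n x K` matrix, columns ordered by decreasing concentration.
#' @export
dpssTapers <- function(n, W, K) {
    key <- sprintf("dpss_%d_%.12g_%d", n, W, K)
    if (!is.null(.pcCache[[key]])) return(.pcCache[[key]])
    if (K < 1L || K > n) stop("K must be in 1..n")
    tvec <- 0:(n - 1)
    A <- diag(((n - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * W))
    off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
    A[cbind(2:n, 1:(n - 1))] <- off
    A[cbind(1:(n - 1), 2:n)] <- off
    ev <- eigen(A, symmetric = TRUE)
    tap <- ev$vectors[, seq_len(K), drop = FALSE]
    for (k in seq_len(K)) {
        v <- tap[, k]
        s <- sum(v)
        flip <- if (abs(s) > 1e-8) s < 0 else v[2] < v[1]
        if (flip) tap[, k] <- -v
    }
    .pcCache[[key]] <- tap
    tap
}

#' Multitaper Fourier coefficients
#'
#' Per trial and taper, the exact DFT of the demeaned, DPSS-tapered signal
#' at the window's native frequency bins (spacing `1 / window length`),
#' restricted to `freqRange`.  Coefficients are scaled by `1/sqrt(n)` so
#' that, per taper, summed squared moduli over all bins equal the tapered
#' signal's energy (Parseval).  The mean is removed per trial and channel
#' before tapering; no other detrending and no zero-padding are applied.
#'
#' @param epochs a windowed [EpochedEEG] (see [selectWindow()]).
#' @param halfBandwidth DPSS smoothing half-bandwidth in Hz (default 2).
#' @param freqRange numeric(2), inclusive frequency range in Hz; must lie
#'   within `[0, srate/2]`.
#' @return a [SpectralCoeffs].
#' @export
multitaperCoeffs <- function(epochs, halfBandwidth = 2, freqRange = c(1, 30)) {
    stopifnot(is(epochs, "EpochedEEG"))
    d <- dim(epochs@data)
    ntr <- d[1]; nch <- d[2]; n <- d[3]
    wl <- n / epochs@srate
    if (freqRange[1] < 0 || freqRange[2] > epochs@srate / 2 + 1e-9)
        stop(sprintf("freqRange [%g, %g] outside [0, %g] (Nyquist)",
                     freqRange[1], freqRange[2], epochs@srate / 2))
    K <- dpssTaperCount(wl, halfBandwidth)
    tap <- dpssTapers(n, halfBandwidth / epochs@srate, K)

    kk <- 0:(n - 1)
    freqs <- kk / wl
    sel <- which(freqs >= freqRange[1] - 1e-9 & freqs <= freqRange[2] + 1e-9)
    if (!length(sel)) stop("freqRange contains no frequency bins")
    nbin <- length(sel)

    # taper-stacked DFT basis, cached: rows = (bin) x (re, im) x (taper)
    bkey <- sprintf("mtbasis_%d_%.12g_%d_%d_%d", n,
                    halfBandwidth / epochs@srate, K, sel[1], sel[nbin])
    B <- .pcCache[[bkey]]
    if (is.null(B)) {
        phase <- outer(kk[sel], 0:(n - 1), function(k, t) -2 * pi * k * t / n)
        Ec <- cos(phase) / sqrt(n)
        Es <- sin(phase) / sqrt(n)
        B <- matrix(0, 2 * nbin * K, n)
        for (k in seq_len(K)) {
            B[(2 * (k - 1)) * nbin + seq_len(nbin), ] <- Ec * rep(tap[, k], each = nbin)
            B[(2 * k - 1) * nbin + seq_len(nbin), ] <- Es * rep(tap[, k], each = nbin)
        }
        .pcCache[[bkey]] <- B
    }

    X <- matrix(aperm(epochs@data, c(3, 2, 1)), nrow = n)  # cols: ch fastest, then trial
    X <- X - rep(colMeans(X), each = n)
    Y <- array(B %*% X, dim = c(nbin, 2, K, nch, ntr))
    coeffs <- aperm(array(complex(real = Y[, 1, , , ], imaginary = Y[, 2, , , ]),
                          dim = c(nbin, K, nch, ntr)), c(4, 2, 3, 1))
    new("SpectralCoeffs", participant = epochs@participant,
        condition = epochs@condition, coeffs = coeffs, freqs = freqs[sel],
        nTapers = K, windowSpan = wl, srate = epochs@srate,
        labels = chanLabels(epochs))
}

#' All unordered channel pairs of a label set
#' @param labels character vector of channel labels.
#' @return two-column character matrix (`chanA`, `chanB`), upper-triangle order.
#' @export
allPairs <- function(labels) {
    idx <- which(upper.tri(matrix(0, length(labels), length(labels))),
                 arr.ind = TRUE)
    cbind(chanA = labels[idx[, 1]], chanB = labels[idx[, 2]])
}

#' Cross-spectral observations for channel pairs
#'
#' For each requested unordered pair (a, b) and frequency bin, the complex
#' observations `X = coeff(a) * Conj(coeff(b))`, pooled over trials and
#' tapers (trial index varying fastest within each taper).  Swapping a pair
#' conjugates its observations (Hermitian symmetry); `a == a` pairs are
#' purely real auto-spectra.
#'
#' @param coeffs a [SpectralCoeffs].
#' @param pairs `"all"` (default: every unordered pair) or a two-column
#'   character matrix of channel labels.
#' @return a [CrossSpectra].
#' @export
crossSpectra <- function(coeffs, pairs = "all") {
    stopifnot(is(coeffs, "SpectralCoeffs"))
    labels <- coeffs@labels
    if (identical(pairs, "all")) {
        pairs <- allPairs(labels)
    } else {
        pairs <- as.matrix(pairs)
        colnames(pairs) <- c("chanA", "chanB")
    }
    ia <- match(pairs[, 1], labels)
    ib <- match(pairs[, 2], labels)
    if (anyNA(ia) || anyNA(ib)) {
        bad <- unique(c(pairs[, 1][is.na(ia)], pairs[, 2][is.na(ib)]))
        stop(sprintf("unknown channel label(s): %s", paste(bad, collapse = ", ")))
    }
    d <- dim(coeffs@coeffs)
    nobs <- d[1] * d[2]
    A <- array(coeffs@coeffs, dim = c(nobs, d[3], d[4]))
    obs <- A[, ia, , drop = FALSE] * Conj(A[, ib, , drop = FALSE])
    new("CrossSpectra", participant = coeffs@participant,
        condition = coeffs@condition, obs = obs, pairs = pairs,
        freqs = coeffs@freqs, labels = labels)
}

#' @rdname accessors
#' @export
setMethod("participant", "SpectralCoeffs", function(object) object@participant)
#' @rdname accessors
#' @export
setMethod("condition", "SpectralCoeffs", function(object) object@condition)
#' @rdname accessors
#' @export
setMethod("chanLabels", "SpectralCoeffs", function(object) object@labels)

#' Bin centre frequencies in Hz
#' @param x a [SpectralCoeffs] or [CrossSpectra].
#' @return numeric vector of bin frequencies.
#' @export
binFreqs <- function(x) x@freqs

#' @rdname accessors
#' @export
setMethod("nObs", "CrossSpectra", function(object) dim(object@obs)[1])

setMethod("show", "SpectralCoeffs", function(object) {
    d <- dim(object@coeffs)
    cat(sprintf("SpectralCoeffs %s / %s: %d trials x %d tapers x %d channels x %d bins (%.3g-%.3g Hz, df = %.4g Hz)\n",
                object@participant, object@condition, d[1], d[2], d[3], d[4],
                min(object@freqs), max(object@freqs), 1 / object@windowSpan))
})

setMethod("show", "CrossSpectra", function(object) {
    d <- dim(object@obs)
    cat(sprintf("CrossSpectra %s / %s: %d observations x %d pairs x %d bins\n",
                object@participant, object@condition, d[1], d[2], d[3]))
})
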