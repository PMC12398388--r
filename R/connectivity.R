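#' Debiased weighted Phase Lag Index (squared-wPLI estimator)
#'
#' Sample-size-debiased estimator of squared wPLI from the imaginary parts
#' of cross-spectral observations.  With the pairwise double sum over
#' ordered observation pairs j != k,
#' `sum Im_j Im_k / sum |Im_j Im_k|`, evaluated in closed form as
#' `((sum Im)^2 - sum Im^2) / ((sum |Im|)^2 - sum Im^2)`.
#' The estimator lies in \[-1, 1\] and may be negative in finite samples
#' (it is unbiased for squared wPLI); it is `NaN` when the denominator is
#' zero, i.e. all imaginary parts vanish (pure zero-lag coupling), and it is
#' invariant to a common rescaling of the observations.
#'
#' @param imObs numeric vector of `Im(X)` observations, length >= 2.
#' @return scalar in \[-1, 1\], or `NaN` when undefined.
#' @examples
#' debiasedWpli(c(1, 1, 1))   # 1: perfectly consistent lag sign
#' debiasedWpli(c(1, -1))     # -1
#' debiasedWpli(c(1, 1, -1))  # -1/3
#' @export
debiasedWpli <- function(imObs) {
    n <- length(imObs)
    if (n < 2L)
        stop("at least 2 observations are required")
    sIm <- sum(imObs)
    sIm2 <- sum(imObs^2)
    sAbs <- sum(abs(imObs))
    den <- sAbs^2 - sIm2
    if (den == 0) return(NaN)
    (sIm^2 - sIm2) / den
}

#' Brute-force debiased wPLI (O(n^2) oracle)
#'
#' Evaluates the defining double sum over all ordered observation pairs
#' `j != k` directly.  Used as an independent cross-check of
#' [debiasedWpli()]; limited to n <= 500.
#'
#' @param imObs numeric vector of `Im(X)` observations, 2..500 values.
#' @return scalar, equal to `debiasedWpli(imObs)` to ~1e-12.
#' @export
bruteForceWpli <- function(imObs) {
    n <- length(imObs)
    if (n < 2L) stop("at least 2 observations are required")
    if (n > 500L) stop("brute-force oracle limited to n <= 500")
    num <- 0; den <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
        if (j == k) next
        num <- num + imObs[j] * imObs[k]
        den <- den + abs(imObs[j] * imObs[k])
    }
    if (den == 0) return(NaN)
    num / den
}

pcBinGroups <- function(freqs, bands) {
    ranges <- bandRanges(bands)
    groups <- lapply(ranges, function(r)
        which(freqs >= r[1] - 1e-9 & freqs <= r[2] + 1e-9))
    empty <- names(groups)[vapply(groups, length, 0L) == 0L]
    if (length(empty))
        stop(sprintf("no frequency bins fall inside band(s): %s",
                     paste(empty, collapse = ", ")))
    groups
}

pcAssembleConn <- function(values, nanCounts, pairs, labels, participant,
                           condition, bandName, nobs) {
    m <- matrix(NA_real_, length(labels), length(labels),
                dimnames = list(labels, labels))
    ia <- match(pairs[, 1], labels)
    ib <- match(pairs[, 2], labels)
    m[cbind(ia, ib)] <- values
    m[cbind(ib, ia)] <- values
    new("ConnMatrix", participant = participant, condition = condition,
        band = bandName, matrix = m, nObs = as.integer(nobs),
        nUndefined = as.integer(sum(nanCounts)))
}

#' @rdname bandConnectivity
#' @export
setMethod("bandConnectivity", signature(x = "CrossSpectra", bands = "BandSet"),
          function(x, bands, ...) {
    groups <- pcBinGroups(x@freqs, bands)
    npair <- nrow(x@pairs)
    out <- list()
    for (bn in names(groups)) {
        bins <- groups[[bn]]
        vals <- numeric(npair)
        nans <- integer(npair)
        for (p in seq_len(npair)) {
            perBin <- vapply(bins, function(b)
                debiasedWpli(Im(x@obs[, p, b])), 0)
            bad <- is.nan(perBin)
            nans[p] <- sum(bad)
            vals[p] <- if (all(bad)) NaN else mean(perBin[!bad])
        }
        if (sum(nans))
            message(sprintf("band %s: %d undefined (zero-lag) bin estimates excluded",
                            bn, sum(nans)))
        out[[bn]] <- pcAssembleConn(vals, nans, x@pairs, x@labels,
                                    x@participant, x@condition, bn,
                                    dim(x@obs)[1])
    }
    out
})

#' @rdname bandConnectivity
#' @param engine `"cpp"` (compiled accumulation, default) or `"r"`
#'   (materialise cross-spectra and use the per-bin R estimator).
#' @param pairs `"all"` or a two-column character matrix of channel labels.
#' @export
setMethod("bandConnectivity", signature(x = "SpectralCoeffs", bands = "BandSet"),
          function(x, bands, pairs = "all", engine = c("cpp", "r"), ...) {
    engine <- match.arg(engine)
    if (engine == "r")
        return(bandConnectivity(crossSpectra(x, pairs), bands))
    labels <- x@labels
    if (identical(pairs, "all")) pairs <- allPairs(labels)
    ia <- match(pairs[, 1], labels)
    ib <- match(pairs[, 2], labels)
    if (anyNA(ia) || anyNA(ib))
        stop("unknown channel label(s) in pairs")
    groups <- pcBinGroups(x@freqs, bands)
    d <- dim(x@coeffs)
    nobs <- d[1] * d[2]
    res <- cpp_band_dwpli(as.vector(x@coeffs), c(nobs, d[3], d[4]),
                          cbind(ia, ib), groups)
    out <- list()
    for (g in seq_along(groups)) {
        bn <- names(groups)[g]
        out[[bn]] <- pcAssembleConn(res$values[, g], res$nanCounts[, g],
                                    pairs, labels, x@participant,
                                    x@condition, bn, nobs)
    }
    out
})

#' @rdname accessors
#' @export
setMethod("participant", "ConnMatrix", function(object) object@participant)
#' @rdname accessors
#' @export
setMethod("condition", "ConnMatrix", function(object) object@condition)
#' @rdname accessors
#' @export
setMethod("band", "ConnMatrix", function(object) object@band)
#' @rdname accessors
#' @export
setMethod("connValues", "ConnMatrix", function(object) object@matrix)
#' @rdname accessors
#' @export
setMethod("nObs", "ConnMatrix", function(object) object@nObs)
#' @rdname accessors
#' @export
setMethod("chanLabels", "ConnMatrix", function(object) rownames(object@matrix))

setMethod("show", "ConnMatrix", function(object) {
    cat(sprintf("%s %s / %s / %s: %d channels, n = %d observations",
                class(object), object@participant, object@condition,
                object@band, nrow(object@matrix), object@nObs))
    if (object@nUndefined)
        cat(sprintf(" (%d undefined bin estimates)", object@nUndefined))
    cat("\n")
})

#' Write / read a connectivity matrix as TSV
#'
#' Square matrix with a channel-label header row and column; the
#' conventional filename pattern is `{participant}_{condition}_{band}.tsv`.
#'
#' @param x a [ConnMatrix].
#' @param path file path.
#' @return `writeConnMatrix`: `path` invisibly; `readConnMatrix`: a
#'   [ConnMatrix] (provenance parsed from the filename when it follows the
#'   conventional pattern).
#' @export
writeConnMatrix <- function(x, path) {
    stopifnot(is(x, "ConnMatrix"))
    m <- x@matrix
    df <- data.frame(channel = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeConnMatrix
#' @export
readConnMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    labels <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(labels, labels)
    parts <- strsplit(sub("\\.tsv$", "", basename(path)), "_")[[1]]
    if (length(parts) < 3L) parts <- c("unknown", "unknown", "unknown")
    new("ConnMatrix", participant = parts[1],
        condition = paste(parts[2:(length(parts) - 1)], collapse = "_"),
        band = parts[length(parts)], matrix = m, nObs = 0L, nUndefined = 0L)
}
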