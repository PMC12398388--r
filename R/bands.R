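#' Construct a set of frequency bands
#'
#' @param ... named length-2 numeric vectors, e.g. `theta = c(4, 8)`.
#'   Ranges are inclusive and must not overlap.
#' @return a [BandSet].
#' @examples
#' bandSet(theta = c(4, 8), beta = c(15, 30))
#' @export
bandSet <- function(...) {
    new("BandSet", bands = list(...))
}

#' Default analysis bands
#'
#' delta 1-3 Hz, theta 4-8 Hz, alpha 9-12 Hz, beta 15-30 Hz.
#'
#' @return a [BandSet].
#' @export
defaultBands <- function() {
    bandSet(delta = c(1, 3), theta = c(4, 8),
            alpha = c(9, 12), beta = c(15, 30))
}

#' @rdname accessors
#' @export
setMethod("bandRanges", "BandSet", function(object) object@bands)

#' Band names of a BandSet
#' @param x a [BandSet].
#' @return character vector of band names.
#' @export
bandNames <- function(x) names(x@bands)

setMethod("show", "BandSet", function(object) {
    cat("BandSet:\n")
    for (nm in names(object@bands))
        cat(sprintf("  %-6s %g-%g Hz\n", nm, object@bands[[nm]][1],
                    object@bands[[nm]][2]))
})
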