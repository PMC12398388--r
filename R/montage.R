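#' Construct a montage
#'
#' @param labels character vector of unique channel labels.
#' @param roiMap named list of character vectors, each a subset of `labels`.
#' @return a [Montage].
#' @examples
#' m <- montage(c("Fz", "Cz", "Pz"), list(frontal = "Fz", central = "Cz"))
#' chanLabels(m)
#' @export
montage <- function(labels, roiMap = list()) {
    new("Montage", labels = as.character(labels), roiMap = roiMap)
}

#' Default 30-channel scalp montage
#'
#' The standard montage used throughout: 16 frontal ROI electrodes
#' (Fp1, Fp2, Fpz, Fz, F3, F4, F7, F8, AF3, AF4, AF7, AF8, FC1, FC2, FC5,
#' FC6), 7 central ROI electrodes (Cz, C3, C4, CP1, CP2, CP5, CP6), and a
#' conventional completion of 7 posterior/temporal electrodes
#' (P3, P4, Pz, T7, T8, O1, O2) to reach 30 scalp channels.  The completion
#' channels are a convention, not a constraint: pass your own [montage()]
#' anywhere a montage is accepted.
#'
#' @return a [Montage] with ROIs "frontal" and "central".
#' @examples
#' defaultMontage()
#' @export
defaultMontage <- function() {
    frontal <- c("Fp1", "Fp2", "Fpz", "Fz", "F3", "F4", "F7", "F8",
                 "AF3", "AF4", "AF7", "AF8", "FC1", "FC2", "FC5", "FC6")
    central <- c("Cz", "C3", "C4", "CP1", "CP2", "CP5", "CP6")
    posterior <- c("P3", "P4", "Pz", "T7", "T8", "O1", "O2")
    montage(c(frontal, central, posterior),
            roiMap = list(frontal = frontal, central = central))
}

#' @rdname accessors
#' @export
setMethod("chanLabels", "Montage", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("roiMap", "Montage", function(object) object@roiMap)

#' Labels belonging to one ROI
#'
#' @param object a [Montage].
#' @param roi ROI name present in `roiMap(object)`.
#' @return character vector of channel labels.
#' @export
roiLabels <- function(object, roi) {
    stopifnot(is(object, "Montage"))
    if (!roi %in% names(object@roiMap))
        stop(sprintf("unknown ROI '%s'; available: %s", roi,
                     paste(names(object@roiMap), collapse = ", ")))
    object@roiMap[[roi]]
}

setMethod("show", "Montage", function(object) {
    cat(sprintf("Montage with %d channels\n", length(object@labels)))
    cat("  ", paste(object@labels, collapse = " "), "\n", sep = "")
    for (nm in names(object@roiMap))
        cat(sprintf("  ROI %s (%d): %s\n", nm, length(object@roiMap[[nm]]),
                    paste(object@roiMap[[nm]], collapse = " ")))
})
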