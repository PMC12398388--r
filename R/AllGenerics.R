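#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: channel labels,
#' ROI map, provenance labels (participant, condition, band), sampling rate,
#' epoch start time, matrix payloads and mask components.
#'
#' @param object an object of one of the package's S4 classes.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chanLabels", function(object) standardGeneric("chanLabels"))
#' @rdname accessors
#' @export
setGeneric("roiMap", function(object) standardGeneric("roiMap"))
#' @rdname accessors
#' @export
setGeneric("participant", function(object) standardGeneric("participant"))
#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("band", function(object) standardGeneric("band"))
#' @rdname accessors
#' @export
setGeneric("srate", function(object) standardGeneric("srate"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("connValues", function(object) standardGeneric("connValues"))
#' @rdname accessors
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("pairList", function(object) standardGeneric("pairList"))
#' @rdname accessors
#' @export
setGeneric("maskedMatrix", function(object) standardGeneric("maskedMatrix"))
#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))
#' @rdname accessors
#' @export
setGeneric("bandRanges", function(object) standardGeneric("bandRanges"))

#' Window an epoch to an analysis interval
#'
#' @param epochs an [EpochedEEG].
#' @param tStart,tEnd window bounds in seconds relative to stimulus onset;
#'   samples with `tStart <= t < tEnd` are retained.  Defaults 0.3 and 4.0 s
#'   (the post-stimulus interval covering sustained emotional processing).
#' @return a windowed [EpochedEEG] with updated `t0`.
#' @export
setGeneric("selectWindow",
           function(epochs, tStart = 0.3, tEnd = 4.0) standardGeneric("selectWindow"))

#' Band-wise debiased-wPLI connectivity
#'
#' Computes the debiased weighted Phase Lag Index per channel pair and
#' frequency bin and averages the per-bin estimates over each band's bins
#' (NaN-undefined bins are excluded from the average and counted).
#'
#' For [CrossSpectra] input the pure-R per-bin estimator is used; for
#' [SpectralCoeffs] input a compiled accumulation over (trial, taper)
#' observations avoids materialising the cross-spectra (identical values,
#' used by the pipeline for speed).
#'
#' @param x a [CrossSpectra] or [SpectralCoeffs] object.
#' @param bands a [BandSet].
#' @param ... passed to methods; the [SpectralCoeffs] method accepts
#'   `pairs` (two-column character matrix, default all unordered pairs).
#' @return a named list of [ConnMatrix], one per band.
#' @export
setGeneric("bandConnectivity", function(x, bands, ...) standardGeneric("bandConnectivity"))
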