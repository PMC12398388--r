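pcStripNat <- function(x) sub("^Nat", "", x)

#' Condition-minus-baseline connectivity differences
#'
#' Elementwise subtraction of each participant's baseline-condition matrix
#' from every non-baseline matrix of the same participant and band.
#' Condition labels are reported without the "Nat" prefix, so the contrasts
#' are named Negative, Reappraise, Suppress.
#'
#' @param conn list of [ConnMatrix] covering, per participant and band, the
#'   baseline condition and at least one non-baseline condition.
#' @param baseline baseline condition label (default "NatNeutral").
#' @return list of [DeltaMatrix].
#' @export
deltaMatrices <- function(conn, baseline = "NatNeutral") {
    parts <- vapply(conn, participant, "")
    conds <- vapply(conn, condition, "")
    bnds <- vapply(conn, band, "")
    out <- list()
    for (p in unique(parts)) {
        for (b in unique(bnds[parts == p])) {
            sel <- which(parts == p & bnds == b)
            bi <- sel[conds[sel] == baseline]
            if (!length(bi))
                stop(sprintf("participant %s has no baseline (%s) matrix for band %s",
                             p, baseline, b))
            others <- sel[conds[sel] != baseline]
            if (!length(others))
                stop(sprintf("participant %s has no non-baseline matrix for band %s", p, b))
            base <- conn[[bi[1]]]@matrix
            for (i in others) {
                d <- conn[[i]]
                dm <- new("DeltaMatrix", participant = p,
                          condition = pcStripNat(d@condition), band = b,
                          matrix = d@matrix - base, nObs = d@nObs,
                          nUndefined = d@nUndefined, baseline = baseline)
                out[[paste(p, dm@condition, b, sep = ".")]] <- dm
            }
        }
    }
    out
}

#' Group-average delta matrices
#'
#' Mean over participants per condition and band; NaN entries are excluded
#' from the mean, with a message reporting how many were dropped.
#'
#' @param deltas list of [DeltaMatrix] from [deltaMatrices()].
#' @return list of group-level [DeltaMatrix] (`participant = "group"`),
#'   one per condition x band.
#' @export
groupDelta <- function(deltas) {
    conds <- vapply(deltas, condition, "")
    bnds <- vapply(deltas, band, "")
    out <- list()
    for (cb in unique(paste(conds, bnds, sep = "."))) {
        sel <- which(paste(conds, bnds, sep = ".") == cb)
        mats <- lapply(deltas[sel], connValues)
        arr <- simplify2array(mats)
        nanDropped <- sum(is.nan(arr))
        m <- apply(arr, c(1, 2), function(v) {
            v <- v[!is.nan(v)]
            if (length(v)) mean(v) else NaN
        })
        if (nanDropped)
            message(sprintf("group %s: %d NaN participant entries excluded", cb, nanDropped))
        ref <- deltas[[sel[1]]]
        out[[cb]] <- new("DeltaMatrix", participant = "group",
                         condition = ref@condition, band = ref@band,
                         matrix = m, nObs = 0L,
                         nUndefined = as.integer(nanDropped),
                         baseline = ref@baseline)
    }
    out
}

#' Data-driven percentile threshold over positive differences
#'
#' Pools all strictly positive off-diagonal delta-wPLI entries across the
#' supplied matrices (by default the individual-level deltas across
#' participants, conditions and pairs) within each band and returns the
#' q-th percentile using midpoint-position order statistics
#' `p_k = (k - 0.5) / n` with linear interpolation (R quantile type 5, the
#' convention of MATLAB's `prctile`).  Negative and zero entries are
#' excluded from the pool.
#'
#' @param deltas list of [DeltaMatrix] (individual-level for the default
#'   pooling; pass group matrices for group pooling).
#' @param q percentile in (0, 100\], default 95.
#' @return named numeric vector: threshold per band.
#' @export
positivePercentileThreshold <- function(deltas, q = 95) {
    if (q <= 0 || q > 100) stop("q must be in (0, 100]")
    bnds <- vapply(deltas, band, "")
    out <- numeric(0)
    for (b in unique(bnds)) {
        pool <- unlist(lapply(deltas[bnds == b], function(d) {
            m <- connValues(d)
            v <- m[upper.tri(m)]
            v[!is.na(v) & v > 0]
        }))
        if (!length(pool))
            stop(sprintf("no strictly positive delta entries in band %s", b))
        out[b] <- stats::quantile(pool, q / 100, type = 5, names = FALSE)
    }
    out
}

#' Threshold a group delta matrix
#'
#' Entries strictly greater than the threshold are retained; all others are
#' set to zero.  The suprathreshold unordered pairs are enumerated in the
#' pair list.  Idempotent: re-masking a masked matrix at the same threshold
#' reproduces it.
#'
#' @param groupDelta a group-level [DeltaMatrix].
#' @param threshold non-negative threshold in delta-wPLI units.
#' @param q the percentile the threshold came from (metadata, default 95).
#' @param pooling pooling mode tag ("individual" or "group").
#' @return a [MaskResult].
#' @export
applyMask <- function(groupDelta, threshold, q = 95, pooling = "individual") {
    stopifnot(is(groupDelta, "DeltaMatrix"))
    if (threshold < 0) stop("threshold must be >= 0")
    m <- connValues(groupDelta)
    labels <- rownames(m)
    keep <- !is.na(m) & m > threshold
    masked <- ifelse(keep, m, 0)
    diag(masked) <- 0
    ut <- which(upper.tri(m) & keep, arr.ind = TRUE)
    pl <- data.frame(chanA = labels[ut[, 1]], chanB = labels[ut[, 2]],
                     delta = m[ut], stringsAsFactors = FALSE)
    new("MaskResult", band = groupDelta@band, condition = groupDelta@condition,
        threshold = threshold, q = q, pairList = pl, maskedMatrix = masked,
        pooling = pooling)
}

#' @rdname accessors
#' @export
setMethod("threshold", "MaskResult", function(object) object@threshold)
#' @rdname accessors
#' @export
setMethod("pairList", "MaskResult", function(object) object@pairList)
#' @rdname accessors
#' @export
setMethod("maskedMatrix", "MaskResult", function(object) object@maskedMatrix)
#' @rdname accessors
#' @export
setMethod("band", "MaskResult", function(object) object@band)
#' @rdname accessors
#' @export
setMethod("condition", "MaskResult", function(object) object@condition)

setMethod("show", "MaskResult", function(object) {
    cat(sprintf("MaskResult %s / %s: threshold %.4g (q = %g, %s pooling), %d suprathreshold pairs\n",
                object@band, object@condition, object@threshold, object@q,
                object@pooling, nrow(object@pairList)))
})

#' Union of suprathreshold pair lists
#'
#' Deduplicated union of the pair lists of several masks (typically the
#' three condition contrasts of one band), keeping each pair's largest
#' delta.  This is the band-level pair set that anchors individual metrics.
#'
#' @param masks list of [MaskResult] for a single band.
#' @return data.frame with columns `chanA`, `chanB`, `delta`.
#' @export
maskUnion <- function(masks) {
    bnds <- unique(vapply(masks, band, ""))
    if (length(bnds) != 1L)
        stop("maskUnion expects masks from a single band")
    pl <- do.call(rbind, lapply(masks, pairList))
    if (!nrow(pl))
        return(pl)
    key <- paste(pmin(pl$chanA, pl$chanB), pmax(pl$chanA, pl$chanB))
    pl <- pl[order(key, -pl$delta), ]
    pl[!duplicated(paste(pmin(pl$chanA, pl$chanB), pmax(pl$chanA, pl$chanB))), ]
}

#' ROI connectivity metrics anchored in a group-level mask
#'
#' For each participant, condition and ROI: the mean of the participant's
#' own delta values over the masked pairs having at least one endpoint in
#' the ROI.  Participant values are not re-thresholded — the group-level
#' mask anchors the individual metrics.  A pair with both endpoints in the
#' ROI is counted once.  When no masked pair touches an ROI the metric is
#' missing (NA) and a warning is logged.
#'
#' @param deltas list of individual [DeltaMatrix] for one band.
#' @param mask a [MaskResult] for the same band, or a pair-list data.frame
#'   (e.g. from [maskUnion()]).
#' @param montage a [Montage] providing the ROI map.
#' @param rois ROI names (default: all in the montage).
#' @return data.frame (participant, condition, band, roi, dwpli, nPairs).
#' @export
roiMetrics <- function(deltas, mask, montage, rois = names(roiMap(montage))) {
    pl <- if (is(mask, "MaskResult")) pairList(mask) else mask
    bnds <- unique(vapply(deltas, band, ""))
    if (length(bnds) != 1L)
        stop("roiMetrics expects deltas from a single band")
    if (is(mask, "MaskResult") && mask@band != bnds)
        stop(sprintf("mask band (%s) does not match deltas band (%s)",
                     mask@band, bnds))
    rows <- list()
    for (d in deltas) {
        m <- connValues(d)
        for (roi in rois) {
            roiLab <- roiLabels(montage, roi)
            qual <- pl[pl$chanA %in% roiLab | pl$chanB %in% roiLab, , drop = FALSE]
            if (!nrow(qual)) {
                warning(sprintf("no masked pair touches ROI '%s' in band %s",
                                roi, bnds), call. = FALSE)
                val <- NA_real_
            } else {
                v <- m[cbind(match(qual$chanA, rownames(m)),
                             match(qual$chanB, colnames(m)))]
                v <- v[!is.nan(v)]
                val <- if (length(v)) mean(v) else NA_real_
            }
            rows[[length(rows) + 1L]] <-
                data.frame(participant = participant(d),
                           condition = condition(d), band = bnds, roi = roi,
                           dwpli = val, nPairs = nrow(qual),
                           stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Long-format model table for mixed-effects fits
#'
#' Joins ROI metrics with participant attachment scores: one row per
#' participant x condition per band x ROI, with columns `participant`,
#' `condition`, `band`, `roi`, `dwpli`, `anxiety`, `avoidance`, `nPairs`.
#' Rows with a missing outcome are retained here and excluded at fit time.
#'
#' @param metrics data.frame from [roiMetrics()] (several bands/ROIs may be
#'   rbind-ed).
#' @param participants cohort data.frame with `id`, `anxiety`, `avoidance`.
#' @return long-format data.frame.
#' @export
buildModelTable <- function(metrics, participants) {
    i <- match(metrics$participant, participants$id)
    if (anyNA(i))
        stop(sprintf("participant(s) without attachment scores: %s",
                     paste(unique(metrics$participant[is.na(i)]), collapse = ", ")))
    data.frame(participant = metrics$participant,
               condition = metrics$condition,
               band = metrics$band, roi = metrics$roi,
               dwpli = metrics$dwpli,
               anxiety = participants$anxiety[i],
               avoidance = participants$avoidance[i],
               nPairs = metrics$nPairs,
               stringsAsFactors = FALSE)
}
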