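# Minimal EDF+C reader/writer: 16-bit samples, one data record per trial,
# one "EDF Annotations" signal carrying a "TRIAL k" marker per record.
# Covers exactly what the cohort serialization needs; not a general-purpose
# EDF library.

pcPadField <- function(x, width) {
    x <- as.character(x)
    if (nchar(x, type = "bytes") > width)
        stop(sprintf("EDF header field too long (%d > %d): '%s'",
                     nchar(x), width, x))
    paste0(x, strrep(" ", width - nchar(x, type = "bytes")))
}

pcFmtNum <- function(x) {
    s <- sprintf("%.6g", x)
    if (nchar(s) > 8) s <- sprintf("%.3g", x)
    s
}

#' Write one EpochedEEG to an EDF+ file
#'
#' Each trial becomes one fixed-duration data record; samples are quantized
#' to 16 bits over a symmetric physical range covering the data, so the
#' round-trip error is below one quantization step.  An "EDF Annotations"
#' signal stores a `TRIAL k` marker at each trial onset.  The epoch start
#' time and condition are carried in the recording-identification field
#' (`t0=<s> cond=<label>`).
#'
#' @param eeg an [EpochedEEG].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readEDF()], [writeCohort()]
#' @export
writeEDF <- function(eeg, path) {
    stopifnot(is(eeg, "EpochedEEG"))
    d <- dim(eeg@data)
    ntr <- d[1]; nch <- d[2]; ns <- d[3]
    labels <- chanLabels(eeg)
    recDur <- ns / eeg@srate
    mx <- max(abs(eeg@data))
    pm <- signif(max(mx * 1.01, 1e-3), 4)
    if (pm < mx) pm <- signif(mx * 1.05, 4)
    annSamples <- 32L                      # 64 bytes of TAL per record
    nsig <- nch + 1L

    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- paste0(
        pcPadField("0", 8),
        pcPadField(eeg@participant, 80),
        pcPadField(sprintf("t0=%.6g cond=%s", eeg@t0, eeg@condition), 80),
        pcPadField("01.01.00", 8),
        pcPadField("00.00.00", 8),
        pcPadField(256L * (nsig + 1L), 8),
        pcPadField("EDF+C", 44),
        pcPadField(ntr, 8),
        pcPadField(pcFmtNum(recDur), 8),
        pcPadField(nsig, 4))
    writeChar(hdr, con, eos = NULL)

    sigField <- function(values, width)
        paste(vapply(values, pcPadField, "", width = width), collapse = "")
    writeChar(paste0(
        sigField(c(labels, "EDF Annotations"), 16),
        sigField(rep("", nsig), 80),                      # transducer
        sigField(c(rep("uV", nch), ""), 8),               # physical dim
        sigField(c(rep(pcFmtNum(-pm), nch), "-1"), 8),    # physical min
        sigField(c(rep(pcFmtNum(pm), nch), "1"), 8),      # physical max
        sigField(rep("-32768", nsig), 8),                 # digital min
        sigField(rep("32767", nsig), 8),                  # digital max
        sigField(rep("", nsig), 80),                      # prefiltering
        sigField(c(rep(ns, nch), annSamples), 8),
        sigField(rep("", nsig), 32)), con, eos = NULL)

    scale <- 65535 / (2 * pm)   # affine map [-pm, pm] -> [-32768, 32767]
    for (tr in seq_len(ntr)) {
        for (ch in seq_len(nch)) {
            v <- as.integer(pmin(pmax(round((eeg@data[tr, ch, ] + pm) * scale) - 32768,
                                      -32768), 32767))
            writeBin(v, con, size = 2L, endian = "little")
        }
        onset <- (tr - 1) * recDur
        tal <- paste0(sprintf("+%.6g", onset), "\x14\x14",
                      sprintf("+%.6g", onset), "\x14",
                      sprintf("TRIAL %d", tr), "\x14")
        talRaw <- charToRaw(tal)
        if (length(talRaw) > 2L * annSamples)
            stop("annotation too long for the annotation signal")
        writeBin(c(talRaw, raw(2L * annSamples - length(talRaw))), con)
    }
    invisible(path)
}

pcReadField <- function(raw, offset, width) {
    trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

#' Read an EDF+ file written by [writeEDF()]
#'
#' @param path EDF file path.
#' @param montage optional [Montage]; if supplied its labels must match the
#'   file's signal labels (any order-preserving match), and its ROI map is
#'   attached to the result.
#' @return an [EpochedEEG].
#' @export
readEDF <- function(path, montage = NULL) {
    if (!file.exists(path)) stop(sprintf("EDF file not found: %s", path))
    sz <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    fixed <- readBin(con, "raw", 256L)
    if (length(fixed) < 256L)
        stop(sprintf("malformed EDF header (file too short): %s", path))
    if (pcReadField(fixed, 0, 8) != "0")
        stop(sprintf("malformed EDF header (bad version field): %s", path))
    patient <- pcReadField(fixed, 8, 80)
    recording <- pcReadField(fixed, 88, 80)
    nRecords <- as.integer(pcReadField(fixed, 236, 8))
    recDur <- as.numeric(pcReadField(fixed, 244, 8))
    nsig <- as.integer(pcReadField(fixed, 252, 4))
    if (is.na(nsig) || nsig < 1L || is.na(nRecords) || nRecords < 1L)
        stop(sprintf("malformed EDF header (signal/record counts): %s", path))

    sigRaw <- readBin(con, "raw", 256L * nsig)
    fld <- function(offset, width)
        vapply(seq_len(nsig) - 1L,
               function(i) pcReadField(sigRaw, offset * nsig + i * width, width),
               "")
    labels <- fld(0, 16)
    physMin <- as.numeric(fld(16 + 80 + 8, 8))
    physMax <- as.numeric(fld(16 + 80 + 8 + 8, 8))
    digMin <- as.numeric(fld(16 + 80 + 8 + 16, 8))
    digMax <- as.numeric(fld(16 + 80 + 8 + 24, 8))
    nSamp <- as.integer(fld(16 + 80 + 8 + 32 + 80, 8))

    annIdx <- which(labels == "EDF Annotations")
    chIdx <- setdiff(seq_len(nsig), annIdx)
    nch <- length(chIdx)
    ns <- nSamp[chIdx[1]]
    if (any(nSamp[chIdx] != ns))
        stop(sprintf("malformed EDF: unequal samples per record across channels: %s", path))
    expect <- 256 * (nsig + 1) + as.numeric(nRecords) * sum(2 * as.numeric(nSamp))
    if (sz < expect)
        stop(sprintf("malformed EDF (truncated data section): %s", path))

    dat <- array(0, dim = c(nRecords, nch, ns))
    trialLabels <- character(0)
    for (r in seq_len(nRecords)) {
        for (s in seq_len(nsig)) {
            if (s %in% annIdx) {
                bytes <- readBin(con, "raw", 2L * nSamp[s])
                txt <- rawToChar(bytes[bytes != as.raw(0)])
                m <- regmatches(txt, regexpr("TRIAL [0-9]+", txt))
                if (length(m)) trialLabels <- c(trialLabels, m)
            } else {
                v <- readBin(con, "integer", nSamp[s], size = 2L,
                             endian = "little")
                g <- (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
                dat[r, match(s, chIdx), ] <- (v - digMin[s]) * g + physMin[s]
            }
        }
    }

    t0 <- 0
    condLabel <- "unknown"
    m <- regmatches(recording, regexec("t0=([-0-9.eE+]+)", recording))[[1]]
    if (length(m) == 2L) t0 <- as.numeric(m[2])
    m <- regmatches(recording, regexec("cond=([^ ]+)", recording))[[1]]
    if (length(m) == 2L) condLabel <- m[2]

    lab <- labels[chIdx]
    if (is.null(montage)) {
        montage <- montage(lab)
    } else if (!identical(chanLabels(montage), lab)) {
        stop(sprintf("montage labels do not match EDF signal labels in %s", path))
    }
    out <- new("EpochedEEG", participant = patient, condition = condLabel,
               data = dat, srate = ns / recDur, t0 = t0, montage = montage)
    attr(out, "trialAnnotations") <- trialLabels
    out
}

#' Write a cohort to disk (EDF+ epochs + participants CSV)
#'
#' One EDF+ file per participant x condition (named
#' `<participant>_<condition>.edf`) plus `participants.csv` with columns
#' `id`, `anxiety`, `avoidance`.
#'
#' @param epochs named list of [EpochedEEG] (as from [simulateEpochs()]).
#' @param participants cohort data.frame from [sampleCohort()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
writeCohort <- function(epochs, participants, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (e in epochs)
        writeEDF(e, file.path(path, sprintf("%s_%s.edf",
                                            e@participant, e@condition)))
    utils::write.csv(participants[, c("id", "anxiety", "avoidance")],
                     file.path(path, "participants.csv"), row.names = FALSE)
    invisible(path)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param path cohort directory.
#' @param montage optional [Montage] to attach (labels must match).
#' @return list with `epochs` (named list of [EpochedEEG]) and
#'   `participants` (data.frame).
#' @export
readCohort <- function(path, montage = NULL) {
    csv <- file.path(path, "participants.csv")
    if (!file.exists(csv))
        stop(sprintf("missing participants.csv in %s", path))
    participants <- utils::read.csv(csv, stringsAsFactors = FALSE)
    for (col in c("id", "anxiety", "avoidance"))
        if (!col %in% names(participants))
            stop(sprintf("participants.csv in %s is missing column '%s'",
                         path, col))
    files <- sort(list.files(path, pattern = "\\.edf$", full.names = TRUE))
    epochs <- lapply(files, readEDF, montage = montage)
    names(epochs) <- vapply(epochs, function(e)
        paste(e@participant, e@condition, sep = "."), "")
    list(epochs = epochs, participants = participants)
}
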