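#' Suprathreshold pair count by brute-force enumeration
#'
#' Counts strictly-above-threshold upper-triangle entries of a symmetric
#' matrix by direct enumeration.  Companion check for [applyMask()].
#'
#' @param m symmetric numeric matrix.
#' @param thr threshold.
#' @return integer count.
#' @export
countSuprathreshold <- function(m, thr) {
    n <- 0L
    for (i in seq_len(nrow(m) - 1L))
        for (j in (i + 1L):ncol(m))
            if (!is.na(m[i, j]) && m[i, j] > thr) n <- n + 1L
    n
}
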