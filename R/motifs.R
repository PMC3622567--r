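#' Control 4-mers used as the comparison panel for ACGT dyads
#'
#' Eight 4-bp control sequences scanned under exactly the same dyad
#' convention as the ACGT core element: TAGC, CGTA, GCTA, ATGC and AGCT,
#' TGCA, CTAG, GATC. Their dyad likelihoods provide the null sample for the
#' Grubbs outlier screen. The motifs are used verbatim; the
#' palindromic/non-palindromic grouping plays no computational role.
#'
#' @return Character vector of the eight control motifs.
#' @examples
#' controlMotifs()
#' @export
controlMotifs <- function() {
    c("TAGC", "CGTA", "GCTA", "ATGC", "AGCT", "TGCA", "CTAG", "GATC")
}

#' The default nine-motif panel: ACGT plus the eight controls
#'
#' @param test Test motif, default "ACGT".
#' @return Character vector of length 9, test motif first.
#' @export
defaultPanel <- function(test = "ACGT") {
    checkMotif(test)
    unique(c(test, controlMotifs()))
}

## validates a motif string: uppercase A/C/G/T only, non-empty
checkMotif <- function(motif) {
    if (!is.character(motif) || length(motif) != 1L || is.na(motif) ||
        nchar(motif) == 0L)
        stop("motif must be a single non-empty string")
    if (grepl("[^ACGT]", motif))
        stop(sprintf("motif '%s' must use only uppercase A, C, G, T", motif))
    invisible(motif)
}
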