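#' @import methods
NULL

#' PromoterSet: fixed-length upstream regions for a set of genes
#'
#' Container for promoter sequences extracted upstream of the translation
#' start codon (ATG). Sequences are stored 5'->3' toward the start codon,
#' so the base immediately preceding the ATG is the last character of each
#' sequence. Promoters truncated by a contig edge are retained with an
#' obtained length shorter than the requested length.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet}, one entry per gene,
#'   named by gene id. Alphabet is restricted to A, C, G, T, N; ambiguity
#'   codes are masked to N on import.
#' @slot speciesLabel Single string identifying the species/assembly.
#' @slot requestedLength The upstream length that was asked for (default
#'   1000 nt); individual sequences may be shorter (contig edge).
#'
#' @seealso [extractUpstream()], [readPromoters()], [scanSet()]
#' @export
setClass("PromoterSet",
    slots = c(
        sequences = "DNAStringSet",
        speciesLabel = "character",
        requestedLength = "integer"
    )
)

setValidity("PromoterSet", function(object) {
    msg <- character()
    if (length(object@speciesLabel) != 1L)
        msg <- c(msg, "speciesLabel must be a single string")
    if (length(object@requestedLength) != 1L || is.na(object@requestedLength) ||
        object@requestedLength < 1L)
        msg <- c(msg, "requestedLength must be a single positive integer")
    nm <- names(object@sequences)
    if (length(object@sequences) > 0L) {
        if (is.null(nm) || any(nm == "") || anyNA(nm))
            msg <- c(msg, "all promoters must be named by gene id")
        else if (anyDuplicated(nm))
            msg <- c(msg, sprintf("duplicate gene id: %s",
                                  nm[duplicated(nm)][1L]))
        if (any(Biostrings::width(object@sequences) >
                object@requestedLength))
            msg <- c(msg, "a sequence is longer than requestedLength")
        bad <- sum(Biostrings::letterFrequency(
            object@sequences, letters = "ACGTN")) !=
            sum(Biostrings::width(object@sequences))
        if (bad)
            msg <- c(msg, "sequences must use only A, C, G, T, N")
    }
    if (length(msg)) msg else TRUE
})

#' SpacerProfile: dyad counts by spacer length
#'
#' Per-motif frequency profile of dyads MOTIF(N)MOTIF for N = 0..maxSpacer
#' over a promoter set: total dyad counts, the number of distinct genes
#' carrying at least one dyad at each N, and the per-1000-promoter
#' normalisation counts * 1000 / nPromoters.
#'
#' @slot motif The core motif scanned (e.g. "ACGT").
#' @slot counts Integer vector indexed N = 0..maxSpacer (names "0".."30"):
#'   total dyad occurrences per spacer length, all ordered occurrence pairs.
#' @slot geneCounts Integer vector, same index: number of distinct genes
#'   with >= 1 dyad at that N.
#' @slot nPromoters Number of promoters scanned (including zero-hit ones).
#' @slot speciesLabel Provenance label copied from the PromoterSet.
#'
#' @export
setClass("SpacerProfile",
    slots = c(
        motif = "character",
        counts = "integer",
        geneCounts = "integer",
        nPromoters = "integer",
        speciesLabel = "character"
    )
)

setValidity("SpacerProfile", function(object) {
    msg <- character()
    if (length(object@motif) != 1L || nchar(object@motif) < 1L)
        msg <- c(msg, "motif must be a single non-empty string")
    if (length(object@nPromoters) != 1L || object@nPromoters < 1L)
        msg <- c(msg, "nPromoters must be a single positive integer")
    if (any(object@counts < 0L)) msg <- c(msg, "counts must be >= 0")
    if (length(object@geneCounts) != length(object@counts))
        msg <- c(msg, "geneCounts and counts must have equal length")
    if (any(object@geneCounts > object@counts))
        msg <- c(msg, "geneCounts cannot exceed counts")
    expected <- as.character(seq_len(length(object@counts)) - 1L)
    if (!identical(names(object@counts), expected))
        msg <- c(msg, "counts must be named \"0\"..\"maxSpacer\"")
    if (length(msg)) msg else TRUE
})

#' SpacerPool: observed spacer sequences grouped by spacer length
#'
#' For each spacer length N, the multiset of spacer strings observed between
#' the two motif copies of every dyad. Feeds position-wise composition and
#' IUPAC consensus generation.
#'
#' @slot motif Core motif the dyads were scanned for.
#' @slot pools Named list, element "N" holding the character vector of
#'   spacers of length N (possibly empty).
#'
#' @export
setClass("SpacerPool",
    slots = c(motif = "character", pools = "list")
)

setValidity("SpacerPool", function(object) {
    msg <- character()
    ns <- suppressWarnings(as.integer(names(object@pools)))
    if (anyNA(ns)) msg <- c(msg, "pool names must be integer spacer lengths")
    else {
        for (i in seq_along(object@pools)) {
            p <- object@pools[[i]]
            if (length(p) && any(nchar(p) != ns[i])) {
                msg <- c(msg, sprintf(
                    "pool %d contains a spacer of the wrong length", ns[i]))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' LikelihoodResult: condition-enrichment statistic for one motif
#'
#' The likelihood-of-occurrence L = X / Y with X = |A intersect B| / |B| and
#' Y = |A| / |universe|, where A is the set of genes regulated by a
#' condition and B the set of genes whose promoter carries a dyad at spacer
#' length N (per-N) or at any N (overall). L = 1 is the value expected under
#' independence of regulation and dyad content.
#'
#' @slot condition Condition label (e.g. "salt_up").
#' @slot direction "up" or "down".
#' @slot motif Core motif of the dyads defining B.
#' @slot perN Numeric vector of L(N) for N = 0..maxSpacer; NA where
#'   |B(N)| = 0 (undefined).
#' @slot overall Overall L using B = union over all N.
#' @slot counts List of the audit counts: nA, nUniverse, nBperN, nABperN,
#'   nBany, nABany.
#'
#' @export
setClass("LikelihoodResult",
    slots = c(
        condition = "character",
        direction = "character",
        motif = "character",
        perN = "numeric",
        overall = "numeric",
        counts = "list"
    )
)

setValidity("LikelihoodResult", function(object) {
    msg <- character()
    if (!object@direction %in% c("up", "down"))
        msg <- c(msg, "direction must be 'up' or 'down'")
    ok <- is.na(object@perN) | object@perN >= 0
    if (!all(ok)) msg <- c(msg, "likelihoods must be >= 0 or NA")
    if (length(msg)) msg else TRUE
})

#' GrubbsResult: single-outlier screen of a motif against controls
#'
#' Grubbs test on the vector of overall likelihoods for the test motif plus
#' the control motifs (n = 9 in the standard panel). The screen calls a
#' condition significant only when the test motif itself is the extreme
#' point and its Grubbs statistic exceeds the critical value.
#'
#' @slot values Named numeric vector of likelihoods, one per motif.
#' @slot testMotif The motif being screened (must be among names(values)).
#' @slot G The Grubbs statistic max |x - mean| / sd.
#' @slot extremeIndex Index of the extreme value in `values`.
#' @slot critical Critical value at the chosen alpha and sidedness.
#' @slot alpha Significance level.
#' @slot sidedness "two_sided" or "one_sided".
#' @slot significant TRUE iff the extreme point is the test motif and
#'   G > critical.
#' @slot center Sample mean of values.
#' @slot scale Sample standard deviation (n - 1 denominator).
#'
#' @export
setClass("GrubbsResult",
    slots = c(
        values = "numeric",
        testMotif = "character",
        G = "numeric",
        extremeIndex = "integer",
        critical = "numeric",
        alpha = "numeric",
        sidedness = "character",
        significant = "logical",
        center = "numeric",
        scale = "numeric"
    )
)

setValidity("GrubbsResult", function(object) {
    msg <- character()
    n <- length(object@values)
    if (n < 3L) msg <- c(msg, "need at least 3 values")
    if (!object@testMotif %in% names(object@values))
        msg <- c(msg, "testMotif must be one of the value names")
    if (object@G > (n - 1) / sqrt(n) + 1e-9)
        msg <- c(msg, "G exceeds its theoretical maximum (n-1)/sqrt(n)")
    if (length(msg)) msg else TRUE
})

#' PercentileOutliers: peak/dip calls on a spacer-frequency profile
#'
#' Spacer lengths whose dyad count lies strictly above the high-percentile
#' whisker (peaks) or strictly below the low-percentile whisker (dips) of
#' the profile's own 31-value distribution.
#'
#' @slot lowPct,highPct Whisker percentiles (defaults 10 and 90).
#' @slot lowWhisker,highWhisker The corresponding quantile values.
#' @slot peaks,dips Integer vectors of spacer lengths N.
#'
#' @export
setClass("PercentileOutliers",
    slots = c(
        lowPct = "numeric", highPct = "numeric",
        lowWhisker = "numeric", highWhisker = "numeric",
        peaks = "integer", dips = "integer"
    )
)

setValidity("PercentileOutliers", function(object) {
    if (length(intersect(object@peaks, object@dips)))
        "peaks and dips must be disjoint" else TRUE
})
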