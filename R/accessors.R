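#' @rdname PromoterSet-class
setMethod("speciesLabel", "PromoterSet", function(x) x@speciesLabel)

#' @rdname PromoterSet-class
setMethod("requestedLength", "PromoterSet", function(x) x@requestedLength)

#' @rdname PromoterSet-class
setMethod("obtainedLengths", "PromoterSet", function(x) {
    w <- Biostrings::width(x@sequences)
    names(w) <- names(x@sequences)
    w
})

#' @rdname PromoterSet-class
setMethod("promoterSequences", "PromoterSet", function(x) x@sequences)

#' @rdname PromoterSet-class
setMethod("geneIds", "PromoterSet", function(x) names(x@sequences))

#' @rdname PromoterSet-class
setMethod("length", "PromoterSet", function(x) length(x@sequences))

#' @rdname PromoterSet-class
#' @param i Index or gene ids to subset by.
setMethod("[", "PromoterSet", function(x, i) {
    initialize(x, sequences = x@sequences[i])
})

#' @rdname PromoterSet-class
setMethod("show", "PromoterSet", function(object) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf(
        "PromoterSet: %d promoters [%s], requested length %d nt\n",
        length(object@sequences), object@speciesLabel,
        object@requestedLength))
    if (length(w))
        cat(sprintf("  obtained length: min %d, max %d; %d truncated\n",
                    min(w), max(w), sum(w < object@requestedLength)))
})

#' @rdname SpacerProfile-class
setMethod("motif", "SpacerProfile", function(x) x@motif)

#' @rdname SpacerProfile-class
setMethod("dyadCounts", "SpacerProfile", function(x) x@counts)

#' @rdname SpacerProfile-class
setMethod("geneDyadCounts", "SpacerProfile", function(x) x@geneCounts)

#' @rdname SpacerProfile-class
setMethod("perThousand", "SpacerProfile", function(x) {
    x@counts * 1000 / x@nPromoters
})

#' @rdname SpacerProfile-class
setMethod("nPromoters", "SpacerProfile", function(x) x@nPromoters)

#' @rdname SpacerProfile-class
setMethod("maxSpacer", "SpacerProfile", function(x) {
    length(x@counts) - 1L
})

#' @rdname SpacerProfile-class
setMethod("speciesLabel", "SpacerProfile", function(x) x@speciesLabel)

#' @rdname SpacerProfile-class
setMethod("show", "SpacerProfile", function(object) {
    cat(sprintf(
        "SpacerProfile: %s(N)%s, N = 0..%d, %d promoters [%s]\n",
        object@motif, object@motif, length(object@counts) - 1L,
        object@nPromoters, object@speciesLabel))
    cat(sprintf("  total dyads: %d (%.1f per 1000 promoters)\n",
                sum(object@counts),
                sum(object@counts) * 1000 / object@nPromoters))
})

#' @rdname SpacerPool-class
setMethod("motif", "SpacerPool", function(x) x@motif)

#' @rdname SpacerPool-class
setMethod("spacers", "SpacerPool", function(x, N) {
    key <- as.character(N)
    if (!key %in% names(x@pools)) character(0) else x@pools[[key]]
})

#' @rdname SpacerPool-class
setMethod("show", "SpacerPool", function(object) {
    n <- vapply(object@pools, length, integer(1))
    cat(sprintf("SpacerPool: motif %s, %d spacer lengths, %d spacers\n",
                object@motif, length(object@pools), sum(n)))
})

#' @rdname LikelihoodResult-class
setMethod("overallLikelihood", "LikelihoodResult", function(x) x@overall)

#' @rdname LikelihoodResult-class
setMethod("perNLikelihood", "LikelihoodResult", function(x) x@perN)

#' @rdname LikelihoodResult-class
setMethod("motif", "LikelihoodResult", function(x) x@motif)

#' @rdname LikelihoodResult-class
setMethod("show", "LikelihoodResult", function(object) {
    cat(sprintf(
        "LikelihoodResult: condition %s (%s), motif %s\n",
        object@condition, object@direction, object@motif))
    cat(sprintf(
        "  overall L = %.4f  (|A| = %d, |B_any| = %d, universe = %d)\n",
        object@overall, object@counts$nA, object@counts$nBany,
        object@counts$nUniverse))
})

#' @rdname PercentileOutliers-class
setMethod("peaks", "PercentileOutliers", function(x) x@peaks)

#' @rdname PercentileOutliers-class
setMethod("dips", "PercentileOutliers", function(x) x@dips)

#' @rdname PercentileOutliers-class
setMethod("show", "PercentileOutliers", function(object) {
    cat(sprintf(
        "PercentileOutliers (%g%%/%g%% whiskers %.3g/%.3g)\n  peaks: %s\n  dips:  %s\n",
        object@lowPct, object@highPct, object@lowWhisker,
        object@highWhisker,
        paste(object@peaks, collapse = ", "),
        paste(object@dips, collapse = ", ")))
})

#' @rdname GrubbsResult-class
setMethod("isSignificant", "GrubbsResult", function(x) x@significant)

#' @rdname GrubbsResult-class
setMethod("show", "GrubbsResult", function(object) {
    cat(sprintf(
        "GrubbsResult: test motif %s, n = %d, %s alpha = %g\n",
        object@testMotif, length(object@values), object@sidedness,
        object@alpha))
    cat(sprintf(
        "  G = %.4f, critical = %.4f, extreme = %s, significant = %s\n",
        object@G, object@critical,
        names(object@values)[object@extremeIndex], object@significant))
})
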