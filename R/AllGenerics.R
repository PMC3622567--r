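#' @rdname PromoterSet-class
#' @param x,object A \linkS4class{PromoterSet} (or other class as documented).
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))

#' @rdname PromoterSet-class
#' @export
setGeneric("requestedLength", function(x) standardGeneric("requestedLength"))

#' @rdname PromoterSet-class
#' @export
setGeneric("obtainedLengths", function(x) standardGeneric("obtainedLengths"))

#' @rdname PromoterSet-class
#' @export
setGeneric("promoterSequences",
           function(x) standardGeneric("promoterSequences"))

#' @rdname PromoterSet-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname SpacerProfile-class
#' @param x A \linkS4class{SpacerProfile} or \linkS4class{SpacerPool}.
#' @export
setGeneric("motif", function(x) standardGeneric("motif"))

#' @rdname SpacerProfile-class
#' @export
setGeneric("dyadCounts", function(x) standardGeneric("dyadCounts"))

#' @rdname SpacerProfile-class
#' @export
setGeneric("geneDyadCounts", function(x) standardGeneric("geneDyadCounts"))

#' @rdname SpacerProfile-class
#' @export
setGeneric("perThousand", function(x) standardGeneric("perThousand"))

#' @rdname SpacerProfile-class
#' @export
setGeneric("nPromoters", function(x) standardGeneric("nPromoters"))

#' @rdname SpacerProfile-class
#' @export
setGeneric("maxSpacer", function(x) standardGeneric("maxSpacer"))

#' @rdname SpacerPool-class
#' @param x A \linkS4class{SpacerPool}.
#' @param N Spacer length to extract.
#' @export
setGeneric("spacers", function(x, N) standardGeneric("spacers"))

#' @rdname LikelihoodResult-class
#' @param x A \linkS4class{LikelihoodResult}.
#' @export
setGeneric("overallLikelihood",
           function(x) standardGeneric("overallLikelihood"))

#' @rdname LikelihoodResult-class
#' @export
setGeneric("perNLikelihood", function(x) standardGeneric("perNLikelihood"))

#' @rdname PercentileOutliers-class
#' @param x A \linkS4class{PercentileOutliers}.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname PercentileOutliers-class
#' @export
setGeneric("dips", function(x) standardGeneric("dips"))

#' @rdname GrubbsResult-class
#' @param x A \linkS4class{GrubbsResult}.
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))
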