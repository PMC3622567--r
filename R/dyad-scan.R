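#' Find all occurrences of a motif in one sequence
#'
#' Exact, overlapping substring search. The base N in the sequence matches
#' nothing.
#'
#' @param sequence Character string or \link[Biostrings]{DNAString}
#'   (uppercase A/C/G/T/N).
#' @param motif Motif string over A/C/G/T.
#' @return Sorted integer vector of 1-based start positions (empty if the
#'   motif is longer than the sequence).
#' @examples
#' findMotifOccurrences("ACGTACGTACGT", "ACGT")  # 1, 5, 9
#' @export
findMotifOccurrences <- function(sequence, motif) {
    checkMotif(motif)
    subject <- if (methods::is(sequence, "DNAString")) sequence
               else Biostrings::DNAString(toupper(as.character(sequence)))
    if (nchar(motif) > length(subject)) return(integer(0))
    BiocGenerics::start(
        Biostrings::matchPattern(motif, subject, fixed = TRUE))
}

## dyad pairing: from sorted occurrence starts, all (ordered) pairs whose
## gap  g = start_j - start_i - m  lies in [0, maxSpacer]; adjacent_only
## restricts to consecutive occurrences.
.pairGaps <- function(occ, m, maxSpacer, mode) {
    if (length(occ) < 2L)
        return(data.frame(first = integer(0), N = integer(0)))
    if (mode == "adjacent_only") {
        first <- occ[-length(occ)]
        gaps <- occ[-1L] - first - m
        keep <- gaps >= 0L & gaps <= maxSpacer
        return(data.frame(first = first[keep], N = gaps[keep]))
    }
    ## all_pairs: every ordered pair (i, j), i < j, with in-range gap
    firsts <- integer(0); gaps <- integer(0)
    for (i in seq_len(length(occ) - 1L)) {
        g <- occ[(i + 1L):length(occ)] - occ[i] - m
        keep <- g >= 0L & g <= maxSpacer
        if (any(keep)) {
            firsts <- c(firsts, rep.int(occ[i], sum(keep)))
            gaps <- c(gaps, g[keep])
        }
    }
    data.frame(first = firsts, N = gaps)
}

#' Scan one promoter for motif dyads
#'
#' Finds every co-occurrence MOTIF(N)MOTIF with 0 <= N <= \code{maxSpacer}.
#' In the default \code{all_pairs} mode every ordered pair of occurrences
#' within range yields a hit (so a run of three occurrences can yield three
#' dyads); \code{adjacent_only} restricts pairing to consecutive
#' occurrences, for sensitivity analysis.
#'
#' @param sequence Promoter string (or DNAString), 5'->3'.
#' @param motif Core motif, e.g. "ACGT".
#' @param maxSpacer Maximum spacer length N (default 30).
#' @param mode "all_pairs" (default) or "adjacent_only".
#' @return data.frame with one row per dyad: \code{N} (spacer length),
#'   \code{start} (1-based position of the first motif copy) and
#'   \code{spacer} (the intervening string, nchar = N).
#' @examples
#' scanPromoter("ACGTAACGTAACGT", "ACGT")
#' @export
scanPromoter <- function(sequence, motif, maxSpacer = 30,
                         mode = c("all_pairs", "adjacent_only")) {
    mode <- match.arg(mode)
    if (maxSpacer < 0) stop("maxSpacer must be >= 0")
    seqChar <- toupper(as.character(sequence))
    occ <- findMotifOccurrences(seqChar, motif)
    m <- nchar(motif)
    pairs <- .pairGaps(occ, m, as.integer(maxSpacer), mode)
    spacer <- if (nrow(pairs)) substring(seqChar, pairs$first + m,
                                         pairs$first + m + pairs$N - 1L)
              else character(0)
    data.frame(N = pairs$N, start = pairs$first, spacer = spacer,
               stringsAsFactors = FALSE)
}

#' Scan a whole promoter set for motif dyads
#'
#' Applies [scanPromoter()] to every promoter and aggregates results into a
#' \linkS4class{SpacerProfile} (counts by spacer length, per-1000
#' normalisation over all promoters including zero-hit ones, and
#' distinct-gene counts) plus a \linkS4class{SpacerPool} of the observed
#' spacer strings, and the per-hit table.
#'
#' @param x A \linkS4class{PromoterSet}.
#' @param motif Core motif.
#' @param maxSpacer Maximum spacer length (default 30).
#' @param mode Dyad pairing mode, see [scanPromoter()].
#' @return List with elements \code{profile} (SpacerProfile), \code{pool}
#'   (SpacerPool), \code{hits} (data.frame gene_id, N, start, spacer) and
#'   \code{universe} (all scanned gene ids).
#' @export
scanSet <- function(x, motif, maxSpacer = 30,
                    mode = c("all_pairs", "adjacent_only")) {
    mode <- match.arg(mode)
    stopifnot(methods::is(x, "PromoterSet"))
    if (length(x) == 0L)
        stop("empty PromoterSet: per-1000 normalization undefined")
    checkMotif(motif)
    maxSpacer <- as.integer(maxSpacer)
    m <- nchar(motif)

    idx <- Biostrings::vmatchPattern(motif, x@sequences, fixed = TRUE)
    starts <- BiocGenerics::start(idx)
    nOcc <- lengths(starts)
    hitRows <- vector("list", sum(nOcc >= 2L))
    k <- 0L
    ids <- names(x@sequences)
    for (i in which(nOcc >= 2L)) {
        pairs <- .pairGaps(starts[[i]], m, maxSpacer, mode)
        if (nrow(pairs) == 0L) next
        seqChar <- as.character(x@sequences[[i]])
        k <- k + 1L
        hitRows[[k]] <- data.frame(
            gene_id = ids[i], N = pairs$N, start = pairs$first,
            spacer = substring(seqChar, pairs$first + m,
                               pairs$first + m + pairs$N - 1L),
            stringsAsFactors = FALSE)
    }
    hits <- if (k) do.call(rbind, hitRows[seq_len(k)])
            else data.frame(gene_id = character(0), N = integer(0),
                            start = integer(0), spacer = character(0),
                            stringsAsFactors = FALSE)

    nm <- as.character(0:maxSpacer)
    counts <- stats::setNames(integer(maxSpacer + 1L), nm)
    geneCounts <- counts
    if (nrow(hits)) {
        tb <- table(factor(hits$N, levels = 0:maxSpacer))
        counts[] <- as.integer(tb)
        gt <- table(factor(hits$N[!duplicated(paste(hits$gene_id, hits$N))],
                           levels = 0:maxSpacer))
        geneCounts[] <- as.integer(gt)
    }
    pools <- lapply(0:maxSpacer, function(n) hits$spacer[hits$N == n])
    names(pools) <- nm

    list(
        profile = methods::new("SpacerProfile", motif = motif,
                               counts = counts, geneCounts = geneCounts,
                               nPromoters = length(x),
                               speciesLabel = x@speciesLabel),
        pool = methods::new("SpacerPool", motif = motif, pools = pools),
        hits = hits,
        universe = ids)
}

#' Scan a promoter set with the full motif panel
#'
#' Runs [scanSet()] once per motif (the ACGT core plus the eight controls by
#' default) under the identical convention, giving the comparison profiles
#' used for the control-vs-test frequency comparison and the Grubbs screen.
#'
#' @param x A \linkS4class{PromoterSet}.
#' @param motifs Character vector of distinct motifs; default
#'   [defaultPanel()].
#' @param maxSpacer Maximum spacer length.
#' @param mode Dyad pairing mode.
#' @return Named list, one \linkS4class{SpacerProfile} per motif.
#' @export
controlPanel <- function(x, motifs = defaultPanel(), maxSpacer = 30,
                         mode = c("all_pairs", "adjacent_only")) {
    mode <- match.arg(mode)
    if (length(motifs) == 0L) stop("empty motif list")
    if (anyDuplicated(motifs))
        stop("duplicate motif in panel: ", motifs[duplicated(motifs)][1L])
    out <- lapply(motifs, function(mm)
        scanSet(x, mm, maxSpacer = maxSpacer, mode = mode)$profile)
    names(out) <- motifs
    out
}

#' Per-motif dyad gene sets by spacer length
#'
#' For each motif in the panel, the map N -> set of gene ids whose promoter
#' contains at least one dyad with spacer length N. This is the "B" event
#' family of the likelihood-of-occurrence statistic.
#'
#' @inheritParams controlPanel
#' @return Named list (motif) of lists: element \code{byN} is a list indexed
#'   "0".."maxSpacer" of gene-id vectors; element \code{any} is their union.
#' @export
dyadGeneSets <- function(x, motifs = defaultPanel(), maxSpacer = 30,
                         mode = c("all_pairs", "adjacent_only")) {
    mode <- match.arg(mode)
    out <- lapply(motifs, function(mm) {
        hits <- scanSet(x, mm, maxSpacer = maxSpacer, mode = mode)$hits
        byN <- lapply(0:maxSpacer, function(n)
            unique(hits$gene_id[hits$N == n]))
        names(byN) <- as.character(0:maxSpacer)
        list(byN = byN, any = unique(hits$gene_id))
    })
    names(out) <- motifs
    out
}
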