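#' Position-wise base composition of a spacer pool
#'
#' Percentage of A, C, G, T at each spacer position (position 1 is the base
#' immediately 3' of the first motif copy). N characters are excluded from
#' both numerator and denominator at their position, so columns over
#' N-free pools sum to 100.
#'
#' @param pool Character vector of spacer strings, all the same length >= 1
#'   (e.g. \code{spacers(sp, N)}).
#' @return Numeric matrix 4 x N, rownames A, C, G, T, entries in [0, 100].
#' @examples
#' positionComposition(c("AG", "AC", "TG", "TC"))
#' @export
positionComposition <- function(pool) {
    if (!length(pool)) stop("empty spacer pool")
    n <- unique(nchar(pool))
    if (length(n) != 1L) stop("spacers must all have the same length")
    if (n == 0L) stop("spacers have length 0: no positions to profile")
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(pool))
    bases <- c("A", "C", "G", "T")
    cnt <- matrix(0, 4L, n, dimnames = list(bases, NULL))
    present <- intersect(bases, rownames(cm))
    cnt[present, ] <- cm[present, , drop = FALSE]
    denom <- colSums(cnt)  # excludes N/other at each position
    if (any(denom == 0))
        message(sprintf("%d position(s) consist only of N", sum(denom == 0)))
    pct <- sweep(cnt, 2L, pmax(denom, 1L), "/") * 100
    pct[, denom == 0] <- 0
    pct
}

#' IUPAC consensus call for one spacer position
#'
#' A base qualifies when its percentage reaches the class threshold: 25%
#' for G or C and 40% for A or T by default (asymmetric thresholds chosen
#' for an approximately 36% GC background). The call is the IUPAC code for
#' the full qualifying set, e.g. \{G\} -> G, \{C, G\} -> S, \{A, G\} -> R;
#' the empty set -> N.
#'
#' @param pct Numeric vector of percentages named A, C, G, T (one
#'   composition column).
#' @param pctGC Threshold for G and C (default 25).
#' @param pctAT Threshold for A and T (default 40).
#' @return Single IUPAC character.
#' @examples
#' consensusPosition(c(A = 10, C = 30, G = 30, T = 30))  # "S"
#' @export
consensusPosition <- function(pct, pctGC = 25, pctAT = 40) {
    if (!all(c("A", "C", "G", "T") %in% names(pct)))
        stop("pct must be named A, C, G, T")
    qual <- c(
        if (pct[["A"]] >= pctAT) "A",
        if (pct[["C"]] >= pctGC) "C",
        if (pct[["G"]] >= pctGC) "G",
        if (pct[["T"]] >= pctAT) "T")
    if (is.null(qual)) return("N")
    Biostrings::mergeIUPACLetters(paste(qual, collapse = ""))
}

#' Consensus spacer sequences for every spacer length
#'
#' Applies the threshold IUPAC rule position-by-position to each non-empty
#' spacer pool, yielding one consensus string per spacer length N, plus the
#' per-N count of positions that resolved to something other than N (the
#' conservation score) and whether the first/last spacer positions are
#' G/C — the flanking-preference summary.
#'
#' @param pool A \linkS4class{SpacerPool}.
#' @param pctGC,pctAT Thresholds as in [consensusPosition()].
#' @return data.frame with columns \code{N}, \code{n_spacers},
#'   \code{consensus}, \code{conserved_positions}, \code{first_is_G},
#'   \code{last_is_C}; N = 0 has an empty consensus. Empty pools are skipped
#'   with a warning.
#' @export
consensusAll <- function(pool, pctGC = 25, pctAT = 40) {
    stopifnot(methods::is(pool, "SpacerPool"))
    Ns <- as.integer(names(pool@pools))
    rows <- list()
    empty <- integer(0)
    for (i in seq_along(Ns)) {
        n <- Ns[i]
        sp <- pool@pools[[i]]
        if (n > 0L && !length(sp)) {
            empty <- c(empty, n)
            next
        }
        cons <- if (n == 0L) "" else {
            pct <- positionComposition(sp)
            paste(vapply(seq_len(ncol(pct)), function(j)
                consensusPosition(pct[, j], pctGC, pctAT),
                character(1)), collapse = "")
        }
        chars <- strsplit(cons, "")[[1L]]
        rows[[length(rows) + 1L]] <- data.frame(
            N = n, n_spacers = length(sp), consensus = cons,
            conserved_positions = sum(chars != "N"),
            first_is_G = n > 0L && chars[1L] == "G",
            last_is_C = n > 0L && chars[n] == "C",
            stringsAsFactors = FALSE)
    }
    if (length(empty))
        warning(sprintf("empty spacer pool(s) skipped for N = %s",
                        paste(empty, collapse = ", ")))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
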