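# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own scanning/statistics code paths:
# occurrence search is plain substring comparison, dyad pairing is a direct
# double loop over index pairs, and Pearson r is the textbook sum formula.

bruteOccurrences <- function(seq, motif) {
    m <- nchar(motif)
    L <- nchar(seq)
    if (m > L) return(integer(0))
    starts <- seq_len(L - m + 1L)
    starts[substring(seq, starts, starts + m - 1L) == motif]
}

bruteScan <- function(seq, motif, maxSpacer = 30) {
    occ <- bruteOccurrences(seq, motif)
    m <- nchar(motif)
    rows <- list()
    for (i in seq_along(occ)) for (j in seq_along(occ)) {
        if (j <= i) next
        g <- occ[j] - occ[i] - m
        if (g >= 0 && g <= maxSpacer)
            rows[[length(rows) + 1L]] <- data.frame(
                N = g, start = occ[i],
                spacer = substring(seq, occ[i] + m, occ[j] - 1L),
                stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(N = integer(0), start = integer(0),
                          spacer = character(0), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[order(out$start, out$N), ]
    rownames(out) <- NULL
    out
}

# textbook sum-formula Pearson coefficient
sumFormulaPearson <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
    num / den
}

randomSeq <- function(len, gc = 0.4, nN = 0) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    if (nN > 0) s[sample(len, nN)] <- "N"
    paste(s, collapse = "")
}

# sequences built from explicit blocks: motif copies placed on a background
# guaranteed free of both `motif` and `other`, so the same placement with
# the other motif yields a construction-identical dyad layout
plantedPair <- function(nSeq, len, positions, motifA, motifB) {
    bgChar <- "T"  # TTTT... contains neither panel motif
    build <- function(motif) {
        vapply(seq_len(nSeq), function(i) {
            chars <- rep(bgChar, len)
            for (p in positions[[i]])
                chars[p:(p + nchar(motif) - 1L)] <-
                    strsplit(motif, "")[[1L]]
            paste(chars, collapse = "")
        }, character(1))
    }
    a <- build(motifA); b <- build(motifB)
    names(a) <- names(b) <- sprintf("g%03d", seq_len(nSeq))
    list(a = a, b = b)
}

expandIupac <- function(code) {
    if (code == "N") return(character(0))
    strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1L]]
}
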