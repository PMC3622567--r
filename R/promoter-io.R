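#' Load a genome FASTA into a sequence store
#'
#' Reads a (multi-)FASTA of chromosomes/contigs. Sequence names are the
#' first whitespace-delimited token of each header. IUPAC ambiguity codes
#' other than N are masked to N (their count is reported via a message);
#' N never matches any motif character downstream.
#'
#' @param path Path to the FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}, alphabet A/C/G/T/N.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test contig", "acgtACGT"), fa)
#' loadGenome(fa)
#' @export
loadGenome <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0L) stop("empty FASTA: ", path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate sequence id in ", path, ": ",
             names(x)[duplicated(names(x))][1L])
    nAmbig <- sum(Biostrings::letterFrequency(
        x, letters = "MRWSYKVHDB", collapse = TRUE))
    if (nAmbig > 0) {
        x <- Biostrings::replaceAmbiguities(x, new = "N")
        message(sprintf("masked %d ambiguous base(s) to N", nAmbig))
    }
    x
}

#' Load gene annotation as a table of translation-start records
#'
#' Two formats are supported. \code{tsv}: four columns gene_id, seq_id,
#' strand, atg_pos (a header line is detected and skipped); atg_pos is the
#' 1-based forward-strand coordinate of the A of the start codon. \code{gff3}:
#' rows of type CDS are grouped by their Parent attribute (falling back to
#' ID) and the translation start is min(start) for + genes and max(end) for
#' - genes; gene features with no CDS are skipped with a warning.
#'
#' @param path Annotation file path.
#' @param format "tsv" or "gff3".
#' @return A data.frame with columns gene_id, seq_id, strand, atg_pos.
#' @export
loadAnnotation <- function(path, format = c("tsv", "gff3")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    genes <- if (format == "tsv") .loadAnnotationTsv(path)
             else .loadAnnotationGff3(path)
    if (anyDuplicated(genes$gene_id))
        stop("duplicate gene_id in annotation: ",
             genes$gene_id[duplicated(genes$gene_id)][1L])
    bad <- !genes$strand %in% c("+", "-")
    if (any(bad))
        stop("invalid strand for gene ", genes$gene_id[bad][1L],
             " (must be + or -)")
    if (anyNA(genes$atg_pos) || any(genes$atg_pos < 1L))
        stop("atg_pos must be a positive integer for every gene")
    rownames(genes) <- NULL
    genes
}

.loadAnnotationTsv <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- grepl("gene_id", first, fixed = TRUE)
    df <- utils::read.delim(path, header = hasHeader,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L)
        stop("gene table must have 4 columns: gene_id, seq_id, strand, atg_pos")
    df <- df[, 1:4]
    names(df) <- c("gene_id", "seq_id", "strand", "atg_pos")
    if (!is.numeric(df$atg_pos)) {
        pos <- suppressWarnings(as.integer(df$atg_pos))
        if (anyNA(pos)) stop("non-integer atg_pos in ", path)
        df$atg_pos <- pos
    } else df$atg_pos <- as.integer(df$atg_pos)
    df$gene_id <- as.character(df$gene_id)
    df$seq_id <- as.character(df$seq_id)
    df$strand <- as.character(df$strand)
    df
}

.loadAnnotationGff3 <- function(path) {
    gff <- rtracklayer::import(path, format = "gff3")
    cds <- gff[gff$type == "CDS"]
    if (length(cds) == 0L) stop("no CDS features in ", path)
    key <- if (!is.null(cds$Parent) && any(lengths(cds$Parent) > 0)) {
        vapply(cds$Parent, function(p)
            if (length(p)) as.character(p[1L]) else NA_character_,
            character(1))
    } else as.character(cds$ID)
    if (anyNA(key)) stop("CDS feature without Parent/ID in ", path)
    st <- as.character(BiocGenerics::strand(cds))
    sq <- as.character(GenomeInfoDb::seqnames(cds))
    starts <- BiocGenerics::start(cds)
    ends <- BiocGenerics::end(cds)
    ids <- unique(key)
    recs <- lapply(ids, function(g) {
        i <- key == g
        strand <- st[i][1L]
        data.frame(
            gene_id = g, seq_id = sq[i][1L], strand = strand,
            atg_pos = if (strand == "+") min(starts[i]) else max(ends[i]),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    geneFeats <- gff[gff$type == "gene"]
    if (length(geneFeats)) {
        noCds <- setdiff(as.character(geneFeats$ID), key)
        if (length(noCds))
            warning(sprintf("%d gene(s) with no CDS skipped (e.g. %s)",
                            length(noCds), noCds[1L]))
    }
    out
}

#' Extract fixed-length upstream (promoter) regions
#'
#' For a + strand gene the promoter is the forward-strand interval
#' \code{[max(1, atg_pos - L), atg_pos - 1]}; for a - strand gene it is the
#' reverse complement of \code{[atg_pos + 1, min(contig_end, atg_pos + L)]}.
#' Either way the returned string reads 5'->3' toward the start codon.
#' Genes truncated by a contig edge are retained with a shorter obtained
#' length; genes whose upstream region is entirely off-contig (e.g. ATG at
#' position 1 on +) are retained with an empty sequence and a warning.
#'
#' @param store Named \link[Biostrings]{DNAStringSet} from [loadGenome()].
#' @param genes Annotation data.frame from [loadAnnotation()].
#' @param requestedLength Upstream length in nt (default 1000).
#' @param speciesLabel Provenance label stored in the result.
#' @return A \linkS4class{PromoterSet}.
#' @export
extractUpstream <- function(store, genes, requestedLength = 1000,
                            speciesLabel = "unlabelled") {
    if (!methods::is(store, "DNAStringSet"))
        stop("store must be a DNAStringSet")
    need <- c("gene_id", "seq_id", "strand", "atg_pos")
    if (!all(need %in% names(genes)))
        stop("genes must have columns ", paste(need, collapse = ", "))
    L <- as.integer(requestedLength)
    if (is.na(L) || L < 1L) stop("requestedLength must be >= 1")
    missing <- setdiff(unique(genes$seq_id), names(store))
    if (length(missing))
        stop("annotation references unknown contig(s): ",
             paste(utils::head(missing, 3), collapse = ", "))
    contigLen <- stats::setNames(Biostrings::width(store), names(store))
    cl <- unname(contigLen[genes$seq_id])
    over <- genes$atg_pos > cl
    if (any(over))
        stop("atg_pos beyond contig length for gene ",
             genes$gene_id[over][1L])
    plus <- genes$strand == "+"
    start <- ifelse(plus, pmax(1L, genes$atg_pos - L), genes$atg_pos + 1L)
    end <- ifelse(plus, genes$atg_pos - 1L, pmin(cl, genes$atg_pos + L))
    w <- pmax(0L, end - start + 1L)
    start <- ifelse(w == 0L, 1L, start)  # placeholder anchor for empties

    seqs <- vector("list", nrow(genes))
    for (ctg in unique(genes$seq_id)) {
        i <- which(genes$seq_id == ctg)
        rr <- IRanges::IRanges(start = start[i], width = w[i])
        seqs[i] <- as.list(Biostrings::extractAt(store[[ctg]], rr))
    }
    out <- methods::as(do.call(c, lapply(seqs, Biostrings::DNAStringSet)),
                       "DNAStringSet")
    if (any(!plus))
        out[!plus] <- Biostrings::reverseComplement(out[!plus])
    names(out) <- genes$gene_id

    nEmpty <- sum(w == 0L)
    nTrunc <- sum(w > 0L & w < L)
    if (nEmpty)
        warning(sprintf("%d promoter(s) empty (ATG at contig edge)", nEmpty))
    if (nTrunc)
        message(sprintf("%d promoter(s) truncated by a contig edge", nTrunc))
    methods::new("PromoterSet", sequences = out,
                 speciesLabel = as.character(speciesLabel),
                 requestedLength = L)
}

#' Write / read a PromoterSet as FASTA
#'
#' The FASTA header encodes the gene id, obtained length, requested length
#' and species label, so that \code{readPromoters(writePromoters(P))}
#' reproduces \code{P} exactly.
#'
#' @param x A \linkS4class{PromoterSet}.
#' @param path Output (input) FASTA path.
#' @return \code{writePromoters} returns \code{path} invisibly;
#'   \code{readPromoters} returns a \linkS4class{PromoterSet}.
#' @export
writePromoters <- function(x, path) {
    stopifnot(methods::is(x, "PromoterSet"))
    out <- x@sequences
    names(out) <- sprintf("%s obtained=%d requested=%d species=%s",
                          names(out), Biostrings::width(out),
                          x@requestedLength, x@speciesLabel)
    Biostrings::writeXStringSet(out, filepath = path)
    invisible(path)
}

#' @rdname writePromoters
#' @export
readPromoters <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    x <- Biostrings::readDNAStringSet(path)
    headers <- names(x)
    names(x) <- sub("\\s.*$", "", headers)
    grab <- function(field, default) {
        m <- regmatches(headers,
                        regexpr(paste0(field, "=\\S+"), headers))
        if (length(m) == length(headers) && length(headers) > 0)
            sub(paste0(field, "="), "", m) else default
    }
    reqs <- grab("requested", NA_character_)
    req <- if (all(is.na(reqs))) max(Biostrings::width(x), 1L)
           else as.integer(reqs[1L])
    sp <- grab("species", "unlabelled")[1L]
    methods::new("PromoterSet", sequences = x,
                 speciesLabel = sp, requestedLength = as.integer(req))
}

#' Construct a PromoterSet from in-memory sequences
#'
#' @param sequences Named character vector or DNAStringSet of promoter
#'   sequences (5'->3' toward the ATG).
#' @param speciesLabel Provenance label.
#' @param requestedLength Requested upstream length; defaults to the longest
#'   sequence supplied.
#' @return A \linkS4class{PromoterSet}.
#' @examples
#' PromoterSet(c(g1 = "ACGTACGT", g2 = "TTTTTTTT"), "toy")
#' @export
PromoterSet <- function(sequences, speciesLabel = "unlabelled",
                        requestedLength = NULL) {
    seqs <- if (methods::is(sequences, "DNAStringSet")) sequences
            else Biostrings::DNAStringSet(toupper(sequences))
    if (is.null(requestedLength))
        requestedLength <- max(Biostrings::width(seqs), 1L)
    methods::new("PromoterSet", sequences = seqs,
                 speciesLabel = as.character(speciesLabel),
                 requestedLength = as.integer(requestedLength))
}
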