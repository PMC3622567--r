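test_that("loadGenome normalizes case, keys by header token, masks ambiguity", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">chr1", "acgt"), fa)
    x <- loadGenome(fa)
    expect_identical(as.character(x), c(chr1 = "ACGT"))

    writeLines(c(">c1 description here", "ACGT", ">c2", "TTTT"), fa)
    expect_identical(names(loadGenome(fa)), c("c1", "c2"))

    writeLines(c(">c1", "ACRT"), fa)
    expect_message(x <- loadGenome(fa), "masked 1")
    expect_identical(as.character(x), c(c1 = "ACNT"))

    writeLines(c(">dup", "ACGT", ">dup", "TTTT"), fa)
    expect_error(loadGenome(fa), "dup")
    writeLines(character(0), fa)
    expect_error(loadGenome(fa))
})

test_that("loadAnnotation parses TSV rows and validates them", {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines("g1\tchr1\t+\t1001", tsv)
    g <- loadAnnotation(tsv, "tsv")
    expect_identical(g, data.frame(gene_id = "g1", seq_id = "chr1",
                                   strand = "+", atg_pos = 1001L))

    writeLines(c("gene_id\tseq_id\tstrand\tatg_pos",
                 "g1\tchr1\t+\t10", "g2\tchr2\t-\t99"), tsv)
    expect_equal(nrow(loadAnnotation(tsv, "tsv")), 2L)

    writeLines(c("g1\tchr1\t+\t10", "g1\tchr1\t-\t99"), tsv)
    expect_error(loadAnnotation(tsv, "tsv"), "duplicate gene_id")
    writeLines("g1\tchr1\t*\t10", tsv)
    expect_error(loadAnnotation(tsv, "tsv"), "strand")
    writeLines("g1\tchr1\t+\tabc", tsv)
    expect_error(loadAnnotation(tsv, "tsv"), "atg_pos")
})

test_that("GFF3 translation start is min(start) on + and max(end) on -", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tsrc\tCDS\t1200\t1500\t.\t+\t0\tID=c1;Parent=g1",
        "chr1\tsrc\tCDS\t1600\t1900\t.\t+\t0\tID=c2;Parent=g1",
        "chr1\tsrc\tCDS\t300\t500\t.\t-\t0\tID=c3;Parent=g2",
        "chr1\tsrc\tCDS\t550\t700\t.\t-\t0\tID=c4;Parent=g2"), gff)
    g <- loadAnnotation(gff, "gff3")
    g <- g[order(g$gene_id), ]
    expect_equal(g$atg_pos, c(1200L, 700L))
    expect_equal(g$strand, c("+", "-"))
})

test_that("GFF3 genes with no CDS are skipped with a warning", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=gNoCds",
        "chr1\tsrc\tgene\t1200\t1900\t.\t+\t.\tID=g1",
        "chr1\tsrc\tCDS\t1200\t1500\t.\t+\t0\tID=c1;Parent=g1"), gff)
    expect_warning(g <- loadAnnotation(gff, "gff3"), "gNoCds")
    expect_identical(g$gene_id, "g1")
})

test_that("upstream extraction honours strand, truncation and edge cases", {
    store <- Biostrings::DNAStringSet(c(c1 = "AAAATGCCCC", c2 = "CATTTT"))
    genes <- data.frame(gene_id = c("gA", "gB"),
                        seq_id = c("c1", "c2"),
                        strand = c("+", "-"), atg_pos = c(5L, 3L))
    ps <- suppressMessages(extractUpstream(store, genes,
                                           requestedLength = 4))
    seqs <- as.character(promoterSequences(ps))
    expect_identical(seqs[["gA"]], "AAAA")
    # minus strand: forward [4,6] = TTT, reverse complement = AAA
    expect_identical(seqs[["gB"]], "AAA")

    # truncation: + strand, ATG at 3 -> obtained length 2
    g2 <- data.frame(gene_id = "gT", seq_id = "c1", strand = "+",
                     atg_pos = 3L)
    expect_message(psT <- extractUpstream(store, g2, 1000), "truncated")
    expect_equal(unname(obtainedLengths(psT)), 2L)
    expect_identical(as.character(promoterSequences(psT))[[1]], "AA")

    # ATG at position 1 on + -> empty promoter kept, with warning
    g3 <- data.frame(gene_id = "gE", seq_id = "c1", strand = "+",
                     atg_pos = 1L)
    expect_warning(psE <- extractUpstream(store, g3, 10), "empty")
    expect_equal(unname(obtainedLengths(psE)), 0L)

    # ATG beyond the contig is an error
    g4 <- data.frame(gene_id = "gX", seq_id = "c2", strand = "+",
                     atg_pos = 99L)
    expect_error(extractUpstream(store, g4, 10), "beyond contig")
})

test_that("extraction is strand-consistent under contig reverse complement", {
    set.seed(11)
    for (rep in 1:5) {
        L <- 60L
        contig <- randomSeq(L, gc = 0.5)
        p <- sample(15:50, 1)
        store <- Biostrings::DNAStringSet(c(ctg = contig))
        plus <- extractUpstream(
            store, data.frame(gene_id = "g", seq_id = "ctg",
                              strand = "+", atg_pos = p),
            requestedLength = 10)
        rcStore <- Biostrings::DNAStringSet(
            c(ctg = as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(contig)))))
        minus <- extractUpstream(
            rcStore, data.frame(gene_id = "g", seq_id = "ctg",
                                strand = "-", atg_pos = L - p + 1L),
            requestedLength = 10)
        expect_identical(as.character(promoterSequences(plus)),
                         as.character(promoterSequences(minus)))
    }
})

test_that("promoter FASTA round-trips exactly, including N and empty sets", {
    ps <- PromoterSet(c(g1 = "ACGTNNACGT", g2 = "TTTT", g3 = ""),
                      speciesLabel = "toy", requestedLength = 10)
    fa <- withr::local_tempfile(fileext = ".fa")
    writePromoters(ps, fa)
    back <- readPromoters(fa)
    expect_identical(as.character(promoterSequences(back)),
                     as.character(promoterSequences(ps)))
    expect_identical(geneIds(back), geneIds(ps))
    expect_identical(requestedLength(back), requestedLength(ps))
    expect_identical(speciesLabel(back), "toy")

    empty <- PromoterSet(character(0), "none", requestedLength = 5)
    writePromoters(empty, fa)
    expect_equal(length(readPromoters(fa)), 0L)
})

test_that("obtained length never exceeds the requested length", {
    set.seed(4)
    contig <- randomSeq(500)
    store <- Biostrings::DNAStringSet(c(c = contig))
    genes <- data.frame(gene_id = sprintf("g%d", 1:20), seq_id = "c",
                        strand = sample(c("+", "-"), 20, TRUE),
                        atg_pos = sample(2:499, 20))
    ps <- suppressMessages(extractUpstream(store, genes, 100))
    expect_true(all(obtainedLengths(ps) <= 100))
    deep <- genes$strand == "+" & genes$atg_pos > 100 |
            genes$strand == "-" & genes$atg_pos <= 400
    expect_true(all(obtainedLengths(ps)[deep] == 100))
})
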