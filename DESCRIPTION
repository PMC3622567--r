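Package: dyadSpacer
Title: Co-Occurring ACGT Cis-Element Dyads in Plant Promoters
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scans promoter sets for co-occurring core motifs of the form
    MOTIF(N)MOTIF (dyads) across spacer lengths N = 0..30, with the ACGT
    core element as the primary motif and eight 4-mer controls. Provides
    upstream-region extraction from genome FASTA plus GFF3/TSV annotation,
    spacer-length frequency profiles with per-1000-promoter normalisation,
    percentile-whisker peak/dip calling, sliding-window Pearson conservation
    statistics between species, ortholog-restricted profiles, position-wise
    spacer composition and threshold-based IUPAC consensus sequences, a
    fold-enrichment (likelihood-of-occurrence) statistic for
    condition-regulated gene sets screened by a Grubbs outlier test against
    the control motifs, and a seeded synthetic-data generator for planted
    dyads, enriched condition sets and correlated multi-species profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: MotifDiscovery, SequenceMatching, Transcription, GeneRegulation
RoxygenNote: 7.3.3
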