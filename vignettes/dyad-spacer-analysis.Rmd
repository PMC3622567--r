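---
title: "Scanning promoters for co-occurring ACGT elements: models and choices"
author: "dyadSpacer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning promoters for co-occurring ACGT elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadSpacer)
```

## The question and the model

The ACGT core element is a recurring 4-bp cis-element in plant promoters,
recognised by bZIP transcription factors; in many characterised promoters it
acts as a *dyad* — two copies separated by a spacer whose length constrains
which factor pairs can bind cooperatively. `dyadSpacer` treats a promoter as
the fixed-length region upstream of the translation start (ATG), scans it
for every co-occurrence `MOTIF(N)MOTIF` with spacer length 0 ≤ N ≤ 30, and
summarises a promoter set as a 31-bin spacer-frequency profile. Everything
downstream — peak calling, cross-species correlation, spacer consensus,
condition enrichment — operates on those profiles and the per-hit records
behind them.

The upstream region is measured from the ATG, not the transcription start
site, so it can include 5'UTR; that is a deliberate modelling choice (start
codons are annotated far more reliably than TSSs across plant genomes) and
all species are treated identically. The spacer cap of 30 bp reflects the
biophysics: cooperatively binding factors are generally spaced within
~25 bp, and nothing in the statistics depends on the cap beyond defining
the profile length.

## Counting convention

A run of three occurrences `ACGT x ACGT y ACGT` is ambiguous: does it hold
two dyads or three? The package's default (`all_pairs`) counts **every
ordered pair** of occurrences whose gap is in range — three dyads here if
both gaps and their spanning gap are ≤ 30. This is the only convention
under which "the count at spacer length N" is well defined when motif
copies nest inside longer spacers, and it makes the scanner exactly
symmetric across motifs, which the control comparison requires. An
`adjacent_only` mode (consecutive occurrences only) is available for
sensitivity analysis. Spacers may themselves contain motif occurrences;
they are not excluded.

Scanning is single-stranded, 5'→3' on the extracted promoter. ACGT is its
own reverse complement, so dyad hits for the primary motif are
strand-symmetric anyway; the eight control motifs are scanned under the
identical convention, which is what matters for the comparison. The base N
(used to mask ambiguity codes at genome load) matches nothing.

Whether one should count dyads or dyad-carrying promoters is also
convention; profiles carry both (`dyadCounts()` and `geneDyadCounts()`),
and the per-1000 normalisation divides total dyad counts by the number of
promoters scanned, including promoters with no hit.

## Peaks, dips and conservation windows

Preferred/avoided spacer lengths are read off a box-and-whiskers view of
the profile's own 31 values: counts strictly above the 90th-percentile
whisker are peaks, strictly below the 10th are dips. Percentiles use linear
interpolation between order statistics (`stats::quantile` type 7); any
reasonable percentile method flags the same gross outliers, and both
whiskers are parameters. A constant profile yields no outliers. Peak calls
are shift-invariant and negate cleanly (peaks of −x are dips of x), which
the tests exercise.

Between-species conservation is summarised by Pearson correlation over
sliding windows of consecutive spacer lengths, width 6 up to the full
profile (351 windows for a 31-bin profile at minimum width 6, enumerated
exhaustively). Each window carries t = r·√((w−2)/(1−r²)) and a two-sided
p-value on w − 2 df; sidedness is not obvious for this kind of screen, so
the conservative two-sided choice is used throughout. Correlations are
computed on raw counts; scaling to per-1000 leaves r unchanged, which is a
tested property rather than an assumption. No multiple-testing correction
is applied across windows — the windows table is an exploratory map, and
consumers should treat the p-values accordingly. Zero-variance windows
(possible when bins are zero at small scale) are skipped with a warning.

Ortholog-group conservation restricts each species' profile to the group's
genes (`subsetProfile()`) and correlates the full 31-bin vectors. Whether a
group profile should be summed counts or per-gene averages is
underdetermined; both are available (per-gene average = counts /
n_promoters), and correlation is indifferent to the choice since it is a
per-species rescaling.

## Spacer consensus

For each spacer length, the position-wise percentages of A, C, G, T are
computed over all observed spacers (over occurrences, not promoters — a
promoter contributing three dyads contributes three spacers). A base
qualifies at a position when its percentage reaches 25% for G/C or 40% for
A/T; the asymmetry compensates for an AT-rich (~36% GC) background, where
equal thresholds would read baseline AT content as signal. The emitted
character is the IUPAC code of the whole qualifying set — single letters
and S arise naturally, and when several bases qualify the union code
(R/Y/W/K/M/V/...) is the unique consistent extension; an empty set is N.
Note one consequence: a perfectly uniform composition (25/25/25/25)
qualifies G and C but not A or T, so large random pools converge to "S",
not "N" — the consensus encodes enrichment relative to the thresholds, not
randomness per se. N characters in spacers are excluded from both numerator
and denominator position-wise. Raising thresholds can only shrink the
qualifying set (tested monotonicity), and a pool of identical strings
returns that string verbatim.

## Condition enrichment and the Grubbs screen

For a condition-regulated gene set A and the dyad-carrying set B within the
scanned universe U, the likelihood of occurrence is

L = (|A∩B| / |B|) / (|A| / |U|)

— equivalently P(regulated | dyad) / P(regulated), or
|A∩B|·|U| / (|A|·|B|). It is 1 under independence, scale-free under gene
duplication, and undefined (reported NA) when B is empty. Per-N likelihoods
use B(N) (genes with a dyad at exactly that spacer length); the overall
likelihood uses the union of B(N) over all N. Conditions with overall
L > 1.30 (configurable; 1.2 is a reasonable choice for smaller gene
universes) proceed to a Grubbs single-outlier test of the nine likelihoods
(test motif + eight controls). The two-sided critical value at n = 9,
α = 0.05 is 2.215, matching classical tables; two-sided is the default
because a control could in principle be the extreme point. Significance
additionally requires the test motif to *be* the extreme point — without
that condition an outlying control would spuriously flag the condition.
This joint requirement makes the null flag rate conservative (≈ α/9 rather
than α when all nine motifs are exchangeable), which the acceptance battery
checks as an upper bound. No multiple-testing correction is applied across
conditions; with tens of conditions screened, a user should expect the
occasional gate-passer by chance.

## The synthetic-data generator

The generator exists so that every stage is testable without downloads. It
emulates: promoters as i.i.d. base sequences at a controllable GC fraction
(default 0.36, the Arabidopsis genome-wide value); planted dyads at chosen
spacer lengths, Poisson-distributed per promoter (a fixed-count mode exists
for exact fixtures) at uniformly chosen non-overlapping offsets;
condition gene sets with a chosen true enrichment factor over dyad-carrying
genes; and k parallel "species" whose planting rates share a base vector
perturbed by unit-mean lognormal noise, with gene ids aligned 1:1 as a
trivial ortholog table.

Ground truth is defined as the scanner's own output on the final sequences
(*post-rescan*), not as the planted counts: background sequence creates
incidental motif occurrences and planted constructs can pair with each
other, so the planted count is a lower bound while the post-rescan profile
is exact, turning oracle tests from probabilistic into bit-exact. A single
user seed drives everything, with deterministic per-promoter substreams so
any subset of a generated set is reproducible on its own.

What it does **not** emulate: real promoter grammar (TATA boxes, CpG-like
structure, nucleosome positioning), dinucleotide composition, repeat
content, shared ancestry between genes, or phylogenetic sequence evolution.
Passing tests on synthetic data therefore demonstrate that the machinery
measures what it claims on data with known truth — not that any particular
biological profile shape will appear in real genomes.

## Numerical and design choices

- External coordinates are 1-based inclusive (GFF3 convention); hit tables
  use 1-based starts as everywhere else in R/Bioconductor.
- GFF3 translation starts: CDS rows grouped by Parent; min(start) on +,
  max(end) on −. Multi-isoform genes resolve to the outermost CDS edge.
- Promoters truncated by a contig edge are retained (with their shorter
  obtained length) rather than dropped: per-1000 normalisation divides by
  promoter count, not base count, so retention preserves gene-level
  comparability; truncation and empty-promoter events are logged.
- Genome ambiguity codes are masked to N at load; N never matches a motif.
- Percentile type 7, two-sided p-values, sample (n−1) standard deviation in
  the Grubbs statistic, ties in the Grubbs extreme broken to the lowest
  index.
- |r| = 1 windows report t = ±Inf and p = 0 rather than erroring, so
  perfectly proportional fixtures are representable.
- Degenerate inputs are errors where a statistic is undefined (empty
  promoter set for per-1000, zero variance for r or Grubbs, empty spacer
  pool for composition) and warnings where a defensible default exists
  (unknown gene ids skipped in subsets, empty pools skipped in consensus).

## Problem sizes in the tests

The shipped tests and the acceptance script use synthetic sets of a few
hundred to a few thousand promoters (1 kb, 36% GC), 1000-sequence scanner
oracle batteries, 200-replicate enrichment simulations, and a four-species
planted family of 150 promoters each; these sizes were chosen so the
statistical assertions have comfortable margins (3-sigma bands, binomial
CIs) while the whole suite stays desk-scale. Scanning a real plant genome
(30k–50k promoters) with the same code is a minutes-scale job; the
workflow is scripted in `inst/scripts/reproduce_genome_scan.R`.

## Known limitations

- Exact matching only: no PWM or fuzzy motif model, no gapped motifs.
- Single-stranded scanning; for non-palindromic controls a reverse-strand
  dyad would go uncounted (by design: all motifs compared under one
  convention).
- The ortholog analysis assumes gene ids are already consistent between
  the annotation, gene lists and ortholog table; no id conversion is done.
- Likelihood results are screening statistics without multiplicity
  control; they prioritise conditions for follow-up rather than establish
  regulation.
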