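test_that("background generation hits the requested GC and is seeded", {
    bg <- generateBackground(100, 500, gcFraction = 0.36, seed = 1)
    freq <- Biostrings::letterFrequency(promoterSequences(bg), "GC",
                                        collapse = TRUE)
    gc <- freq / (100 * 500)
    # binomial 3-sigma band around 0.36 at 50,000 bases
    expect_lt(abs(gc - 0.36), 3 * sqrt(0.36 * 0.64 / 50000))

    onlyGC <- generateBackground(5, 200, gcFraction = 1.0, seed = 2)
    expect_equal(
        sum(Biostrings::letterFrequency(promoterSequences(onlyGC), "GC")),
        1000L, ignore_attr = TRUE)

    again <- generateBackground(100, 500, gcFraction = 0.36, seed = 1)
    expect_identical(as.character(promoterSequences(bg)),
                     as.character(promoterSequences(again)))
})

test_that("per-promoter substreams make subsets reproducible", {
    big <- generateBackground(10, 100, seed = 7)
    small <- generateBackground(4, 100, seed = 7)
    expect_identical(as.character(promoterSequences(big))[1:4],
                     as.character(promoterSequences(small)))
})

test_that("planting writes exact constructs and defines ground truth by rescan", {
    bg <- generateBackground(50, 300, seed = 3)
    pl <- plantDyads(bg, c(`0` = 1.0), seed = 3, fixedCounts = TRUE)
    # every promoter got exactly one N=0 construct
    expect_equal(nrow(pl$planted), 50L)
    # rescan reproduces the stored post-scan profile bit-exactly
    rescan <- scanSet(pl$promoters, "ACGT")
    expect_identical(dyadCounts(rescan$profile),
                     dyadCounts(pl$postScan$profile))
    # background can only add dyads beyond the planted ones
    expect_gte(unname(dyadCounts(pl$postScan$profile)[["0"]]), 50L)
    # planted constructs are literally present
    seqs <- as.character(promoterSequences(pl$promoters))
    for (i in seq_len(nrow(pl$planted))) {
        p <- pl$planted[i, ]
        expect_identical(substring(seqs[[p$gene_id]], p$start, p$start + 7L),
                         "ACGTACGT")
    }
})

test_that("empty planting rates leave the background untouched", {
    bg <- generateBackground(20, 200, seed = 5)
    pl <- plantDyads(bg, setNames(numeric(0), character(0)), seed = 5)
    expect_identical(as.character(promoterSequences(pl$promoters)),
                     as.character(promoterSequences(bg)))
    expect_identical(dyadCounts(pl$postScan$profile),
                     dyadCounts(scanSet(bg, "ACGT")$profile))
})

test_that("Poisson planting recovers the requested rate within CI", {
    bg <- generateBackground(2000, 400, seed = 11)
    bgRate <- dyadCounts(scanSet(bg, "ACGT")$profile)[["7"]] / 2000
    pl <- plantDyads(bg, c(`7` = 0.5), seed = 11)
    got <- dyadCounts(pl$postScan$profile)[["7"]] / 2000
    # planted Poisson(0.5) per promoter plus (approximately) the background:
    # 3-sigma Poisson band on the total count
    expected <- 0.5 + bgRate
    expect_lt(abs(got - expected), 3 * sqrt(expected / 2000) + 0.02)
})

test_that("infeasible packing is an error naming the promoter", {
    bg <- generateBackground(1, 30, seed = 13)
    expect_error(plantDyads(bg, c(`0` = 10), seed = 13,
                            fixedCounts = TRUE), "g00001")
    expect_error(plantDyads(bg, c(`40` = 1), seed = 13,
                            fixedCounts = TRUE), "too short")
})

test_that("condition generator plants the requested fold", {
    set.seed(0)
    u <- sprintf("g%05d", 1:10000)
    B <- sample(u, 1000)
    cs <- generateConditionSets(u, B, pRegulated = 0.2, fold = 2.0,
                                seed = 21)
    lr <- likelihood(cs$genes, list(`0` = B), u)
    expect_equal(overallLikelihood(lr), 2.0, tolerance = 0.15)
    # fold 1 is the independence null
    cs1 <- generateConditionSets(u, B, pRegulated = 0.2, fold = 1.0,
                                 seed = 22)
    expect_equal(overallLikelihood(likelihood(cs1$genes, list(`0` = B), u)),
                 1.0, tolerance = 0.15)
    # p = 1 regulates everything, so L = 1 exactly
    csAll <- generateConditionSets(u, B, pRegulated = 1, fold = 1,
                                   seed = 23)
    expect_identical(sort(csAll$genes), sort(u))
    expect_error(generateConditionSets(u, B, 0.6, 2.0, seed = 24),
                 "exceeds 1")
})

test_that("species families share profiles at zero noise and are seeded", {
    fam <- generateSpeciesFamily(2, 60, c(`7` = 1.0), profileNoise = 0,
                                 seed = 31, promoterLength = 300)
    c1 <- dyadCounts(fam$species1$postScan$profile)
    c2 <- dyadCounts(fam$species2$postScan$profile)
    expect_gt(pearsonR(as.numeric(c1), as.numeric(c2)), 0.9)
    expect_identical(geneIds(fam$species1$promoters),
                     geneIds(fam$species2$promoters))
    fam2 <- generateSpeciesFamily(2, 60, c(`7` = 1.0), profileNoise = 0,
                                  seed = 31, promoterLength = 300)
    expect_identical(
        as.character(promoterSequences(fam$species2$promoters)),
        as.character(promoterSequences(fam2$species2$promoters)))
    expect_error(generateSpeciesFamily(1, 10, c(`7` = 1), seed = 1),
                 "at least 2")
})
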