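test_that("likelihood of occurrence follows X/Y with auditable counts", {
    u <- sprintf("g%03d", 1:100)
    A <- u[1:20]
    B5 <- u[c(1:4, 31:36)]          # |B| = 10, |A n B| = 4
    lr <- likelihood(A, list(`5` = B5), u)
    expect_equal(unname(perNLikelihood(lr)[["5"]]), 2.0)
    expect_equal(lr@counts$nA, 20L)
    expect_equal(unname(lr@counts$nBperN[["5"]]), 10L)
    expect_equal(unname(lr@counts$nABperN[["5"]]), 4L)
    # equivalent closed form |AnB| |U| / (|A| |B|)
    expect_equal(unname(perNLikelihood(lr)[["5"]]),
                 4 * 100 / (20 * 10))
})

test_that("likelihood is 1 when everything is regulated and NA for empty B", {
    u <- sprintf("g%02d", 1:50)
    lr <- likelihood(u, list(`0` = u[1:7], `1` = character(0)), u)
    expect_equal(unname(perNLikelihood(lr)[["0"]]), 1)
    expect_true(is.na(perNLikelihood(lr)[["1"]]))
    expect_equal(overallLikelihood(lr), 1)
    expect_error(likelihood(character(0), list(`0` = u[1:5]), u), "empty")
    expect_error(likelihood("not_in_universe", list(`0` = u[1:5]), u),
                 "subset")
})

test_that("likelihood is invariant under duplicating every gene", {
    u <- sprintf("g%02d", 1:40)
    A <- u[1:10]; B <- u[c(1:5, 20:28)]
    l1 <- likelihood(A, list(`3` = B), u)
    dup <- function(x) c(x, paste0(x, "_copy"))
    l2 <- likelihood(dup(A), list(`3` = dup(B)), dup(u))
    expect_equal(perNLikelihood(l1), perNLikelihood(l2))
    expect_equal(overallLikelihood(l1), overallLikelihood(l2))
})

test_that("likelihood concentrates near 1 for independent sets", {
    set.seed(41)
    u <- sprintf("g%06d", 1:100000)
    A <- sample(u, 20000)
    B <- sample(u, 10000)
    lr <- likelihood(A, list(`0` = B), u)
    # se of L under independence is ~ sqrt(0.8 / (0.2 * 10000)) ~ 0.02
    expect_equal(overallLikelihood(lr), 1, tolerance = 0.08)
})

test_that("Grubbs statistic matches hand computation and its bound", {
    v <- c(rep(1, 8), 2)
    st <- grubbsStatistic(v)
    expect_equal(st$G, 8 / 3, tolerance = 1e-12)
    expect_equal(st$extreme_index, 9L)
    # symmetric data: tie broken to the lowest index
    st2 <- grubbsStatistic(c(-1, 0, 1))
    expect_equal(st2$G, 1)
    expect_equal(st2$extreme_index, 1L)
    # affine invariance
    st3 <- grubbsStatistic(5 * v + 11)
    expect_equal(st3$G, st$G)
    expect_error(grubbsStatistic(rep(3, 5)), "zero standard deviation")
    # theoretical bound (n-1)/sqrt(n)
    set.seed(2)
    for (i in 1:20) {
        x <- rnorm(sample(3:12, 1))
        expect_lte(grubbsStatistic(x)$G,
                   (length(x) - 1) / sqrt(length(x)))
    }
})

test_that("Grubbs critical values match classical tables", {
    expect_equal(grubbsCritical(9, 0.05, "two_sided"), 2.21,
                 tolerance = 0.01 / 2.21)
    expect_equal(grubbsCritical(9, 0.05, "one_sided"), 2.11,
                 tolerance = 0.01 / 2.11)
    expect_equal(grubbsCritical(3, 0.05, "two_sided"), 1.15,
                 tolerance = 0.01 / 1.15)
    # decreasing in alpha, increasing in n
    expect_gt(grubbsCritical(9, 0.01), grubbsCritical(9, 0.10))
    ns <- c(5, 9, 15, 30, 100)
    crit <- vapply(ns, grubbsCritical, numeric(1))
    expect_true(all(diff(crit) > 0))
})

test_that("the screen flags only a test-motif extreme above critical", {
    vals <- c(ACGT = 2.0, a = 1.0, b = 0.98, c = 1.02, d = 1.0,
              e = 0.99, f = 1.01, g = 1.0, h = 1.0)
    gr <- grubbsScreen(vals, "ACGT")
    expect_true(isSignificant(gr))
    expect_gt(gr@G, gr@critical)
    # an extreme control never flags the condition
    vals2 <- c(ACGT = 1.0, a = 2.0, b = 0.98, c = 1.02, d = 1.0,
               e = 0.99, f = 1.01, g = 1.0, h = 1.0)
    expect_false(isSignificant(grubbsScreen(vals2, "ACGT")))
})

test_that("condition screen recovers planted enrichment and gates at 1.30", {
    set.seed(61)
    u <- sprintf("g%05d", 1:8000)
    panel <- lapply(defaultPanel(), function(mm)
        list(byN = list(`0` = sample(u, 800)), any = NULL))
    names(panel) <- defaultPanel()
    panel <- lapply(panel, function(p) {
        p$any <- p$byN[["0"]]; p
    })
    enriched <- generateConditionSets(u, panel$ACGT$byN[["0"]],
                                      pRegulated = 0.2, fold = 2.0,
                                      seed = 99, condition = "salt_up")
    nullCond <- generateConditionSets(u, character(0), pRegulated = 0.2,
                                      fold = 1.0, seed = 100,
                                      condition = "independent")
    weak <- list(condition = "weak", direction = "up",
                 genes = sample(u, 1000))
    out <- conditionScreen(list(enriched, nullCond, weak), panel, u)
    expect_true(out$significant[out$condition == "salt_up"])
    expect_gt(out$L_ACGT[out$condition == "salt_up"], 1.30)
    expect_false(out$significant[out$condition == "independent"])
    # a condition below the gate never reaches the Grubbs stage
    expect_false(out$gate_passed[out$condition == "weak"])
    expect_true(is.na(out$G[out$condition == "weak"]))
})

test_that("condition manifests load gene lists relative to the manifest", {
    d <- withr::local_tempdir()
    writeLines(c("g1", "g2", " g3 ", ""), file.path(d, "salt.txt"))
    write.table(data.frame(condition = "salt", direction = "up",
                           path = "salt.txt"),
                file.path(d, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cs <- readConditionManifest(file.path(d, "manifest.tsv"))
    expect_length(cs, 1L)
    expect_identical(cs[[1]]$genes, c("g1", "g2", "g3"))
})
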