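test_that("the binomial vote handles caps, ties and errors", {
    expect_equal(twoTailedBinomialP(1, 1), 1)       # capped symmetric vote
    expect_equal(twoTailedBinomialP(3, 3), 1)
    expect_error(twoTailedBinomialP(0, 0), "at least one")
    ## symmetry
    expect_equal(twoTailedBinomialP(9, 2), twoTailedBinomialP(2, 9))
    ## agreement with an exact arbitrary-precision style recomputation
    for (v in list(c(5, 1), c(10, 3), c(25, 7))) {
        n <- sum(v); k <- max(v)
        exact <- min(1, 2 * sum(choose(n, k:n)) / 2^n)
        expect_equal(twoTailedBinomialP(v[1], v[2]), exact, tolerance = 1e-12)
        expect_equal(negLog10BinomialP(v[1], v[2]), -log10(exact),
                     tolerance = 1e-9)
    }
})

test_that("summaries count signs, skip zero votes and flag degeneracies", {
    v <- data.frame(deltaS = c(5, -2, 0, 7, 3),
                    deltaD1 = c(1, 2, 3, 4, 5) / 10,
                    deltaD2 = c(2, 2, 2, 2, 2) / 10,
                    excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                    usable = rep(TRUE, 5))
    noEx <- summarizeVerdicts(v, useExclusion = FALSE)
    expect_equal(noEx$n1, 3); expect_equal(noEx$n2, 1)
    expect_equal(noEx$deltaSMean, mean(c(5, -2, 0, 7, 3)))
    expect_equal(noEx$deltaDMean1, mean(v$deltaD1))
    withEx <- summarizeVerdicts(v, useExclusion = TRUE)
    expect_equal(withEx$n1, 2); expect_equal(withEx$n2, 1)
    expect_equal(withEx$nRetained, 4)

    single <- data.frame(deltaS = 5, deltaD1 = 0.1, deltaD2 = 0.2,
                         excluded = FALSE, usable = TRUE)
    s <- summarizeVerdicts(single)
    expect_equal(s$deltaSMean, 5)
    expect_equal(s$deltaSSd, 0)
    expect_match(s$flags, "SD undefined", all = FALSE)

    zero <- data.frame(deltaS = c(0, 0), deltaD1 = 0, deltaD2 = 0,
                       excluded = FALSE, usable = TRUE)
    z <- summarizeVerdicts(zero)
    expect_equal(z$binomialP, 1)
    expect_match(z$flags, "no vote", all = FALSE)
})

test_that("comparing an MSA to itself yields zero deltas and no vote", {
    fix <- localComparisonFixture()
    rep1 <- suppressWarnings(compareMsas(
        fix$gold@msa, fix$gold@msa, fix$structures,
        config = ecompassConfig(z = 8),
        scores1 = fix$scores1, scores2 = fix$scores1,
        structureRows = cbind(1:3, 1:3)))
    vd <- verdicts(rep1)
    expect_equal(vd$deltaS, rep(0, 3))
    b <- comparisonSummary(rep1, "without")
    expect_equal(b$n1, 0); expect_equal(b$n2, 0)
    expect_equal(b$binomialP, 1)
})

test_that("swapping the MSAs negates deltas and preserves the vote P", {
    fix <- localComparisonFixture()
    cfg <- ecompassConfig(z = 8)
    fwd <- suppressWarnings(compareMsas(
        fix$gold@msa, fix$corrupted, fix$structures, config = cfg,
        scores1 = fix$scores1, scores2 = fix$scores2,
        structureRows = cbind(1:3, 1:3)))
    rev <- suppressWarnings(compareMsas(
        fix$corrupted, fix$gold@msa, fix$structures, config = cfg,
        scores1 = fix$scores2, scores2 = fix$scores1,
        structureRows = cbind(1:3, 1:3)))
    expect_equal(verdicts(fwd)$deltaS, -verdicts(rev)$deltaS)
    for (blk in c("with", "without")) {
        bf <- comparisonSummary(fwd, blk); br <- comparisonSummary(rev, blk)
        expect_equal(bf$deltaSMean, -br$deltaSMean)
        expect_equal(bf$n1, br$n2)
        expect_equal(bf$n2, br$n1)
        expect_equal(bf$binomialP, br$binomialP)
    }
    ## the gold standard wins against its corruption
    expect_gt(comparisonSummary(fwd, "without")$deltaSMean, 0)
})

test_that("exclusion flags derive from the distance tables alone", {
    fix <- localComparisonFixture()
    rep1 <- suppressWarnings(compareMsas(
        fix$gold@msa, fix$corrupted, fix$structures,
        config = ecompassConfig(z = 8),
        scores1 = fix$scores1, scores2 = fix$scores2,
        structureRows = cbind(1:3, 1:3)))
    dd <- rep1@deltaD
    expect_setequal(verdicts(rep1)$structure[verdicts(rep1)$excluded],
                    union(dd$msa1@excluded, dd$msa2@excluded))
    ## identical geometry anchored at three records: no outliers possible
    expect_length(dd$msa1@excluded, 0L)
    ## re-running exclusion on the per-structure values alone reproduces
    ## the flags: delta-S never enters
    redo <- iterativeExclusion(deltaDFromValues(
        setNames(dd$msa1@perStructure, dd$msa1@structureIds)))
    expect_identical(redo@excluded, dd$msa1@excluded)
})

test_that("sequence-set mismatches fall back to the shared subset", {
    m1 <- toyMsa(c("ACDEFGHIKL", "MNPQRSTVWY", "ACDEFGHIKW"),
                 ids = c("x", "y", "z"))
    m2 <- toyMsa(c("MNPQRSTVWY", "ACDEFGHIKL"), ids = c("p", "q"))
    expect_warning(res <- ecompass:::intersectSequenceSets(m1, m2),
                   "shared subset")
    expect_equal(msaLength(res$msa1), 2L)
    expect_identical(ecompass:::ungappedSeqs(res$msa1),
                     ecompass:::ungappedSeqs(res$msa2))
})

test_that("reports serialize to TSV and JSON", {
    fix <- localComparisonFixture()
    rep1 <- suppressWarnings(compareMsas(
        fix$gold@msa, fix$corrupted, fix$structures,
        config = ecompassConfig(z = 8),
        scores1 = fix$scores1, scores2 = fix$scores2,
        structureRows = cbind(1:3, 1:3)))
    prefix <- tempfile()
    paths <- writeReport(rep1, prefix)
    expect_true(all(file.exists(paths)))
    vd <- read.delim(paste0(prefix, ".verdicts.tsv"))
    expect_equal(nrow(vd), 3L)
    js <- jsonlite::read_json(paste0(prefix, ".report.json"))
    expect_equal(js$with_exclusion$n1,
                 comparisonSummary(rep1, "with")$n1)
    expect_match(js$note, "discounted")
})
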