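test_that("planted models are seed-deterministic with valid geometry", {
    pm1 <- makePlantedModel(50, 40, seed = 111)
    pm2 <- makePlantedModel(50, 40, seed = 111)
    expect_identical(pm1@contactGraph, pm2@contactGraph)
    expect_identical(pm1@potts@fields, pm2@potts@fields)
    expect_identical(pm1@pseudoStructure@caCoords, pm2@pseudoStructure@caCoords)

    ## planted pairs respect separation >= 6 and lie within 8 Angstrom
    cg <- pm1@contactGraph
    expect_equal(nrow(cg), 40L)
    expect_true(all(cg[, 2] - cg[, 1] >= 6))
    d <- caDistanceMatrix(pm1@pseudoStructure)
    expect_true(all(d[cg] <= 8))
    ## couplings are zero off the contact graph by construction (only
    ## contact pairs carry blocks at all)
    expect_equal(nrow(pm1@potts@pairs), 40L)
    expect_identical(pm1@potts@pairs[, 1], cg[, 1])
})

test_that("sampling is seeded, gap-free and matches field marginals when uncoupled", {
    pm <- makePlantedModel(12, 0, seed = 121)
    g1 <- sampleMsa(pm, n = 300, seed = 122)
    g2 <- sampleMsa(pm, n = 300, seed = 122)
    expect_identical(g1@msa@seqs, g2@msa@seqs)
    expect_false(any(grepl("[-.]", g1@msa@seqs)))
    expect_error(sampleMsa(pm, n = 0), "positive")

    ## with no couplings the sampler draws independent softmax(fields)
    gBig <- sampleMsa(pm, n = 2000, burnIn = 100, thin = 2, seed = 123)
    X <- ecompass:::msaStateMatrix(gBig@msa)
    for (col in c(1, 7, 12)) {
        emp <- tabulate(X[, col], 21)[1:20] / nrow(X)
        theo <- exp(pm@potts@fields[1:20, col])
        theo <- theo / sum(theo)
        expect_lt(max(abs(emp - theo)), 0.05)
    }
    ## and pairwise frequencies factorize
    X1 <- X[, 3]; X2 <- X[, 9]
    f12 <- table(factor(X1, 1:20), factor(X2, 1:20)) / nrow(X)
    f1 <- tabulate(X1, 20) / nrow(X); f2 <- tabulate(X2, 20) / nrow(X)
    expect_lt(max(abs(f12 - outer(f1, f2))), 0.05)
})

test_that("the Gibbs sampler reproduces the exact Boltzmann law on a toy model", {
    ## 2 columns, 3 active states, one coupled pair: the joint law is
    ## enumerable exactly
    q <- 21
    fields <- matrix(0, q, 2)
    fields[1:3, 1] <- c(0.4, -0.2, 0)
    fields[1:3, 2] <- c(-0.3, 0.5, 0)
    J <- array(0, dim = c(q, q, 1))
    set.seed(131)
    J[1:3, 1:3, 1] <- matrix(rnorm(9, 0, 0.7), 3, 3)
    X <- ecompass:::gibbs_sample_cpp(fields, cbind(1L, 2L), J, nSample = 3L,
                                     n = 100000L, burnin = 100L, thin = 2L,
                                     seed = 132L)
    emp <- table(factor(X[, 1], 1:3), factor(X[, 2], 1:3)) / nrow(X)
    logw <- outer(fields[1:3, 1], fields[1:3, 2], "+") + J[1:3, 1:3, 1]
    theo <- exp(logw) / sum(exp(logw))
    se <- sqrt(theo * (1 - theo) / nrow(X))
    ## thinned single-chain draws: allow 5 standard errors
    expect_true(all(abs(emp - theo) < 5 * se + 1e-3))
})

test_that("corruption is nested, monotone in fraction and id-preserving", {
    pm <- makePlantedModel(40, 25, seed = 141)
    gold <- sampleMsa(pm, n = 120, seed = 142)
    expect_equal(spScore(gold, gold@msa), 1)

    c0 <- corruptAlignment(gold, 0, maxShift = 3, seed = 143)
    expect_equal(spScore(gold, c0), 1)

    sps <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f)
        spScore(gold, corruptAlignment(gold, f, maxShift = 3, seed = 143)),
        numeric(1))
    expect_true(all(diff(sps) < 0))
    expect_equal(sps[1], 1)

    ## shift-based corruption of a gap-free gold standard preserves shared
    ## prefixes and within-register co-alignment, so full corruption
    ## floors around 0.4-0.5 rather than 0
    heavy <- corruptAlignment(gold, 1, maxShift = 40, seed = 144)
    expect_lt(spScore(gold, heavy), 0.6)
    expect_identical(sort(ecompass:::ungappedSeqs(heavy)),
                     sort(ecompass:::ungappedSeqs(gold@msa)))

    ## protected records keep their row intact (up to trailing padding)
    prot <- corruptAlignment(gold, 1, maxShift = 3, seed = 145, protect = 1L)
    row1 <- sub("-+$", "", unname(msaSeqs(prot)[1]))
    expect_identical(row1, unname(msaSeqs(gold@msa)[1]))
})

test_that("sum-of-pairs agreement matches a brute-force co-alignment count", {
    gold <- toyMsa(c("ACDE", "AC-E", "A-DE"), ids = c("x", "y", "z"))
    test <- toyMsa(c("ACDE-", "-AC-E", "A--DE"), ids = c("x", "y", "z"))
    ## brute-force oracle over all sequence pairs and columns
    bf <- function(m1, m2) {
        maps1 <- lapply(seq_len(msaLength(m1)), function(s) {
            cc <- ecompass:::residueColumns(m1, s)
            setNames(seq_along(cc), cc)
        })
        maps2 <- lapply(seq_len(msaLength(m2)), function(s) {
            cc <- ecompass:::residueColumns(m2, s)
            setNames(seq_along(cc), cc)
        })
        num <- den <- 0
        for (s in 1:(msaLength(m1) - 1)) for (t in (s + 1):msaLength(m1)) {
            for (col in seq_len(msaWidth(m1))) {
                rs <- maps1[[s]][as.character(col)]
                rt <- maps1[[t]][as.character(col)]
                if (is.na(rs) || is.na(rt)) next
                den <- den + 1
                ## columns of these residues in the test alignment
                cs <- ecompass:::residueColumns(m2, s)[rs]
                ct <- ecompass:::residueColumns(m2, t)[rt]
                if (cs == ct) num <- num + 1
            }
        }
        num / den
    }
    expect_equal(spScore(gold, test), bf(gold, test))
    expect_equal(spScore(gold, gold), 1)
    ## a test alignment sharing no co-aligned pair scores zero
    none <- toyMsa(c("ACDE--------", "----AC-E----", "--------A-DE"),
                   ids = c("x", "y", "z"))
    expect_equal(spScore(gold, none), 0)
    expect_error(spScore(gold, toyMsa(c("AAAA", "CCCC", "GGGG"),
                                      ids = c("x", "y", "z"))),
                 "same sequence set")
})

test_that("the S/S0 ratio is 1 for an uncorrupted copy and below 1 + noise otherwise", {
    pm <- makePlantedModel(40, 28, seed = 151)
    res <- sRatioExperiment(list(pm), corruptionGrid = c(0, 0.5),
                            n = 200, seed = 152)
    expect_equal(res$ratio[res$fraction == 0], 1)
    expect_equal(res$sp[res$fraction == 0], 1)
    ## corrupted alignments never beat the gold standard materially
    expect_true(all(res$sTest <= res$sGold + 0.5))
    expect_lt(res$sp[res$fraction == 0.5], 1)
})
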