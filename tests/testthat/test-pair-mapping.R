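test_that("structure rows are located by exhaustive window search", {
    m <- toyMsa(c("AC-DEFG", "ACWDEFG", "WWWWWWW"))
    ## exact ungapped match -> offset 0
    s <- beadStructure("s1", "ACDEFG")
    loc <- locateStructureRow(s, m)
    expect_equal(loc$row, 1L)
    expect_equal(loc$offset, 0L)

    ## internal window of a longer record
    set.seed(71)
    long <- paste(sample(ecompass:::AA_ORDER, 120, TRUE), collapse = "")
    m2 <- toyMsa(c(long, paste(rev(strsplit(long, "")[[1]]), collapse = "")))
    win <- substr(long, 41, 90)
    s2 <- beadStructure("s2", win)
    loc2 <- locateStructureRow(s2, m2)
    ## brute-force oracle over all records and offsets
    best <- NULL
    for (r in 1:2) {
        u <- strsplit(c(long, paste(rev(strsplit(long, "")[[1]]),
                                    collapse = ""))[r], "")[[1]]
        for (off in 0:(120 - 50)) {
            mm <- sum(u[off + 1:50] != strsplit(win, "")[[1]])
            if (is.null(best) || mm < best$mm)
                best <- list(row = r, offset = off, mm = mm)
        }
    }
    expect_equal(loc2$row, best$row)
    expect_equal(loc2$offset, best$offset)
    expect_equal(loc2$offset, 40L)

    ## absent sequence -> warning and NULL
    s3 <- beadStructure("s3", "MMMMMMMM")
    expect_warning(res <- locateStructureRow(s3, m2), "no MSA record")
    expect_null(res)
})

test_that("separation filter yields exactly the enumerated candidate pairs", {
    ## R = {1..10}, m = 5: pairs with b - a >= 6 are (1,7)..(1,10), (2,8)..,
    ## (3,9), (3,10), (4,10) -> 10 pairs
    set.seed(72)
    width <- 10
    seqs <- replicate(3, paste(sample(ecompass:::AA_ORDER, width, TRUE),
                               collapse = ""))
    m1 <- toyMsa(seqs); m2 <- toyMsa(seqs)
    s <- beadStructure("s", seqs[1])
    map <- buildStructureMap(s, m1, m2)
    expect_equal(map@rSet, 1:10)
    sc <- matrix(runif(100), 10, 10); sc <- (sc + t(sc)) / 2; diag(sc) <- NA
    cs <- new("CouplingScores", scores = sc, nCols = 10L, metadata = list())
    arrs <- buildPairArrays(map, cs, cs, s, m = 5L, z = 4)
    expect_equal(arrs$k1@L, 10L)
    got <- pairEntries(arrs$k1)[, c("a", "b")]
    got <- got[order(got$a, got$b), ]
    oracle <- expand.grid(a = 1:10, b = 1:10)
    oracle <- oracle[oracle$b - oracle$a >= 6, c("a", "b")]
    oracle <- oracle[order(oracle$a, oracle$b), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(oracle)))
})

test_that("the two pair arrays share entries, L and D but not order", {
    fix <- localComparisonFixture()
    s <- fix$structures[[1]]
    map <- buildStructureMap(s, fix$gold@msa, fix$corrupted,
                             rows = c(1L, 1L))
    arrs <- buildPairArrays(map, fix$scores1, fix$scores2, s, m = 5L, z = 8)
    expect_equal(arrs$k1@L, arrs$k2@L)
    expect_equal(arrs$k1@D, arrs$k2@D)
    e1 <- pairEntries(arrs$k1); e2 <- pairEntries(arrs$k2)
    k1set <- e1[order(e1$a, e1$b), c("a", "b", "dist", "distinguished")]
    k2set <- e2[order(e2$a, e2$b), c("a", "b", "dist", "distinguished")]
    rownames(k1set) <- rownames(k2set) <- NULL
    expect_equal(k1set, k2set)
    ## sorted by own DC score descending
    expect_true(!is.unsorted(rev(e1$dc)))
    expect_true(!is.unsorted(rev(e2$dc)))
})

test_that("raising the separation never increases L", {
    fix <- localComparisonFixture()
    s <- fix$structures[[1]]
    map <- buildStructureMap(s, fix$gold@msa, fix$gold@msa, rows = c(1L, 1L))
    Ls <- vapply(c(0L, 3L, 5L, 10L), function(m)
        buildPairArrays(map, fix$scores1, fix$scores1, s, m = m,
                        z = 8)$k1@L, integer(1))
    expect_true(all(diff(Ls) <= 0))
})

test_that("structures aligned only to masked columns are unusable", {
    m1 <- toyMsa(c("ACDEFGHIKL", "WWWWWWWWWW"))
    m1@columnMask <- rep(FALSE, 10)
    m2 <- toyMsa(c("ACDEFGHIKL", "WWWWWWWWWW"))
    s <- beadStructure("s", "ACDEFGHIKL")
    map <- buildStructureMap(s, m1, m2)
    expect_length(map@rSet, 0L)
    sc <- new("CouplingScores", scores = matrix(NA_real_, 10, 10),
              nCols = 10L, metadata = list())
    expect_warning(res <- buildPairArrays(map, sc, sc, s), "unusable")
    expect_null(res)
})
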