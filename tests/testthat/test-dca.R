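test_that("sequence weights match a brute-force neighbour count", {
    ## N identical records -> every weight 1/N, meff 1
    m <- toyMsa(rep("ACDEF", 4))
    w <- computeWeights(m, 0.8)
    expect_equal(seqWeights(w), rep(0.25, 4))
    expect_equal(meff(w), 1)

    ## all records mutually below threshold -> all weights 1
    m2 <- toyMsa(c("AAAAA", "CCCCC", "DDDDD"))
    expect_equal(seqWeights(computeWeights(m2, 0.8)), rep(1, 3))

    ## random 5-record toy vs quadratic-scan oracle (nulls are mismatches)
    set.seed(21)
    seqs <- replicate(5, paste(sample(c("A", "C", "-"), 10, TRUE),
                               collapse = ""))
    m3 <- toyMsa(seqs)
    w3 <- seqWeights(computeWeights(m3, 0.6))
    chars <- strsplit(seqs, "")
    idOracle <- function(x, y) mean(x == y & x != "-" & y != "-")
    ## the record itself always belongs to its own cluster, even when gaps
    ## push its self-identity below the threshold
    oracle <- vapply(1:5, function(s)
        1 / (1 + sum(vapply(setdiff(1:5, s), function(t)
            idOracle(chars[[s]], chars[[t]]) >= 0.6, logical(1)))), numeric(1))
    expect_equal(w3, oracle)

    expect_error(computeWeights(m3, 0), "threshold")
    expect_error(computeWeights(m3, 1.2), "threshold")
})

test_that("pseudo-likelihood gradient matches finite differences", {
    set.seed(5)
    N <- 15; L <- 5; q <- 21
    X <- matrix(sample(1:21, N * L, TRUE), N, L)
    w <- runif(N, 0.2, 1)
    npar <- q * L + choose(L, 2) * q * q
    par <- rnorm(npar, 0, 0.15)
    og <- ecompass:::plm_obj_grad_cpp(par, X, w, 0.01, 0.2 * (L - 1))
    idx <- sample(npar, 25)
    fd <- vapply(idx, function(k) {
        e <- 1e-5
        p1 <- par; p1[k] <- p1[k] + e
        p2 <- par; p2[k] <- p2[k] - e
        (ecompass:::plm_obj_grad_cpp(p1, X, w, 0.01, 0.2 * (L - 1))$value -
         ecompass:::plm_obj_grad_cpp(p2, X, w, 0.01, 0.2 * (L - 1))$value) /
            (2 * e)
    }, numeric(1))
    expect_lt(max(abs(fd - og$grad[idx]) / pmax(abs(fd), 1e-8)), 1e-4)
})

test_that("deterministic covariation lifts the coupled pair to the top score", {
    ## column 2 determines column 5; other columns independent noise
    set.seed(31)
    n <- 200
    partner <- c(A = "W", C = "Y", D = "V")
    s2 <- sample(names(partner), n, TRUE)
    seqs <- vapply(seq_len(n), function(i)
        paste0(sample(c("A", "C", "D"), 1), s2[i],
               sample(c("E", "F", "G"), 1), sample(c("H", "I", "K"), 1),
               partner[s2[i]], sample(c("L", "M", "N"), 1)), character(1))
    m <- toyMsa(seqs)
    sc <- dcScores(frobeniusApc(fitPotts(m, computeWeights(m))))
    top <- arrayInd(which.max(sc), dim(sc))
    expect_setequal(as.integer(top), c(2L, 5L))
})

test_that("a single-record fit is regularizer-dominated with near-zero couplings", {
    m <- toyMsa("ACDEF")
    fit <- suppressWarnings(fitPotts(m, computeWeights(m)))
    ## the pairwise signal of one sequence is absorbed almost entirely by
    ## the (lightly penalized) fields; couplings stay near zero
    expect_lt(max(abs(fit@couplings)), 0.15)
    expect_lt(max(abs(fit@couplings)), 0.05 * max(abs(fit@fields)))
})

test_that("APC correction reproduces hand arithmetic and preserves symmetry", {
    Fm <- matrix(c(NA, 2, 1,
                   2, NA, 1,
                   1, 1, NA), 3, 3)
    apc <- apcCorrect(Fm)
    expect_equal(apc[1, 2], 2 - (1.5 * 1.5) / (4 / 3))
    expect_equal(apc[1, 2], 0.3125)
    expect_equal(apc[1, 3], 1 - (1.5 * 1) / (4 / 3))
    expect_equal(apc[2, 3], 1 - (1.5 * 1) / (4 / 3))
    expect_equal(apc, t(apc))

    ## constant F -> APC identically zero
    Fc <- matrix(3, 4, 4)
    apc0 <- apcCorrect(Fc)
    expect_equal(max(abs(apc0), na.rm = TRUE), 0)

    ## symmetric for any symmetric input
    set.seed(13)
    S <- matrix(runif(25), 5, 5); S <- S + t(S)
    expect_equal(apcCorrect(S), t(apcCorrect(S)))
})

test_that("score matrix import validates dimensions and symmetry", {
    m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
    f <- tempfile()
    write.table(m, f, row.names = FALSE, col.names = FALSE)
    sc <- importScores(f, 3L)
    expect_equal(dcScores(sc)[1, 2], 1)
    expect_equal(dcScores(sc)[2, 3], 3)
    expect_identical(sc@metadata$source, "imported")

    expect_error(importScores(f, 4L), "scored columns")

    m2 <- m; m2[1, 2] <- 1.5
    f2 <- tempfile()
    write.table(m2, f2, row.names = FALSE, col.names = FALSE)
    expect_error(importScores(f2, 3L), "asymmetry")

    ## tiny asymmetry is averaged away silently
    m3 <- m; m3[1, 2] <- 1 + 5e-7
    f3 <- tempfile()
    write.table(format(m3, digits = 12), f3, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    expect_equal(dcScores(importScores(f3, 3L))[1, 2], 1 + 2.5e-7)

    ## export/import round trip
    f4 <- tempfile()
    exportScores(sc, f4)
    expect_equal(dcScores(importScores(f4, 3L)), dcScores(sc))
})

test_that("DC scores are invariant to record order and duplicate insertion", {
    set.seed(41)
    pm <- makePlantedModel(12, 8, couplingScale = 1.2, seed = 401)
    gs <- sampleMsa(pm, n = 80, seed = 402)
    m <- gs@msa
    sc <- dcScores(frobeniusApc(fitPotts(m, computeWeights(m))))

    perm <- sample(msaLength(m))
    mPerm <- ecompass:::newMsaSubset(m, perm)
    scPerm <- dcScores(frobeniusApc(fitPotts(mPerm, computeWeights(mPerm))))
    expect_lt(max(abs(sc - scPerm), na.rm = TRUE), 1e-3)

    ## duplicating a record redistributes its weight, leaving the weighted
    ## objective (hence the scores) unchanged
    mDup <- ecompass:::newMsa(c(msaIds(m), "dup"),
                              c(m@seqs, m@seqs[1]))
    scDup <- dcScores(frobeniusApc(fitPotts(mDup, computeWeights(mDup))))
    expect_lt(max(abs(sc - scDup), na.rm = TRUE), 1e-3)
})

test_that("independent columns yield no enrichment over a shuffled control", {
    set.seed(51)
    n <- 500; L <- 10
    seqs <- replicate(n, paste(sample(ecompass:::AA_ORDER, L, TRUE),
                               collapse = ""))
    m <- toyMsa(seqs)
    sc <- dcScores(frobeniusApc(fitPotts(m, computeWeights(m))))
    ## column-shuffled control destroys any residual covariation
    chars <- do.call(rbind, strsplit(seqs, ""))
    for (j in seq_len(L)) chars[, j] <- chars[sample(n), j]
    mShuf <- toyMsa(apply(chars, 1, paste, collapse = ""))
    scS <- dcScores(frobeniusApc(fitPotts(mShuf, computeWeights(mShuf))))
    ## the top independent-column score should look like the shuffled top
    expect_lt(max(sc, na.rm = TRUE), 2 * max(abs(scS), na.rm = TRUE) + 0.05)
})
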