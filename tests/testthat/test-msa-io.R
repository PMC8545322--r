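test_that("plain FASTA parses with an all-true mask and errors on ragged input", {
    f <- writeFasta(c(a = "AC-D", b = "AC-D"))
    m <- readMsa(f, "fasta")
    expect_s4_class(m, "Msa")
    expect_equal(msaLength(m), 2L)
    expect_equal(msaWidth(m), 4L)
    expect_true(all(columnMask(m)))
    expect_identical(m@dialect, "flush")

    bad <- writeFasta(c(a = "ACDE", b = "ACDEF"))
    expect_error(readMsa(bad, "fasta"), "ragged")
    empty <- tempfile(fileext = ".fa")
    file.create(empty)
    expect_error(readMsa(empty, "fasta"))
})

test_that("A2M insert columns are unscored and sequences uppercased", {
    f <- writeFasta(c(a = "AcD-", b = "GcE-", c = "W.YC"))
    m <- readMsa(f, "a2m")
    ## column 2 is lowercase/dot in every record -> insert, unscored
    expect_identical(columnMask(m), c(TRUE, FALSE, TRUE, TRUE))
    expect_identical(m@dialect, "match_state")
    expect_identical(unname(msaSeqs(m)[1]), "ACD-")
    ## filterNullColumns must not touch a match-state mask
    expect_identical(columnMask(filterNullColumns(m)), columnMask(m))
})

test_that("Stockholm reader honors the #=GC RF reference line", {
    f <- tempfile(fileext = ".sto")
    writeLines(c("# STOCKHOLM 1.0",
                 "seq1 ACD-E",
                 "seq2 ACDYE",
                 "#=GC RF xxx.x",
                 "//"), f)
    m <- readMsa(f, "stockholm")
    expect_identical(columnMask(m), c(TRUE, TRUE, TRUE, FALSE, TRUE))
    expect_identical(m@dialect, "match_state")
    expect_equal(msaIds(m), c("seq1", "seq2"))
})

test_that("writeMsa round-trips records and mask in both formats", {
    m <- toyMsa(c("AC-DE", "ACWDE", "AC-D-"))
    m@columnMask <- c(TRUE, TRUE, FALSE, TRUE, TRUE)

    fa <- tempfile(fileext = ".fa")
    writeMsa(m, fa, "fasta")
    m2 <- readMsa(fa, "fasta")
    expect_identical(msaSeqs(m2), msaSeqs(m))

    sto <- tempfile(fileext = ".sto")
    writeMsa(m, sto, "stockholm")
    m3 <- readMsa(sto, "stockholm")
    expect_identical(msaSeqs(m3), msaSeqs(m))
    expect_identical(columnMask(m3), columnMask(m))

    maskTrack <- tempfile()
    writeMsa(m, fa, "fasta", maskPath = maskTrack)
    expect_identical(scan(maskTrack, integer(), quiet = TRUE),
                     as.integer(m@columnMask))
})

test_that("null-column filtering is strict, mask-only and idempotent", {
    ## 4 sequences: column 1 has 3/4 nulls (dropped), column 2 exactly 2/4
    ## (retained by the strict > rule), column 3 none
    m <- toyMsa(c("-AC", "--C", "-AC", "A-C"))
    f1 <- filterNullColumns(m)
    expect_identical(columnMask(f1), c(FALSE, TRUE, TRUE))
    expect_identical(f1@seqs, m@seqs)
    expect_identical(columnMask(filterNullColumns(f1)), columnMask(f1))

    allRes <- filterNullColumns(toyMsa(c("ACD", "WYV")))
    expect_true(all(columnMask(allRes)))
})

test_that("redundancy purge matches a brute-force identity clustering", {
    m <- toyMsa(c("AAAA", "AAAA"))
    expect_equal(msaLength(purgeRedundancy(m)), 1L)

    m2 <- toyMsa(c("ACDEF", "ACDEY"))   # identity 0.8 < 0.95
    expect_equal(msaLength(purgeRedundancy(m2)), 2L)

    ## 10 records in 3 duplicate groups plus 4 singletons -> 7 survivors
    set.seed(7)
    base <- replicate(3, paste(sample(ecompass:::AA_ORDER, 12, TRUE),
                               collapse = ""))
    singles <- replicate(4, paste(sample(ecompass:::AA_ORDER, 12, TRUE),
                                  collapse = ""))
    seqs <- c(base[1], base[1], base[2], base[2], base[3], base[3], singles)
    m3 <- toyMsa(seqs)
    purged <- purgeRedundancy(m3, 0.95)
    ## brute-force oracle: greedy first-wins over the all-pairs identity matrix
    chars <- strsplit(seqs, "")
    ident <- function(x, y) mean(x == y)
    kept <- 1L
    for (i in 2:length(seqs)) {
        if (all(vapply(kept, function(j) ident(chars[[j]], chars[[i]]) < 0.95,
                       logical(1))))
            kept <- c(kept, i)
    }
    expect_equal(msaLength(purged), length(kept))
    expect_identical(msaIds(purged), paste0("r", kept))
})

test_that("purge survivor count is monotone non-increasing in the cutoff", {
    set.seed(11)
    seqs <- replicate(12, paste(sample(c("A", "C", "D"), 10, TRUE),
                                collapse = ""))
    m <- toyMsa(seqs)
    sizes <- vapply(c(0.5, 0.7, 0.9, 1.0),
                    function(ct) msaLength(purgeRedundancy(m, ct)), numeric(1))
    expect_true(all(diff(sizes) >= 0))
})
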