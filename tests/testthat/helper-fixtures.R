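## Shared fixtures and independent oracles for the test suite. Everything
## is generated in code; no binary data.

## --- alignments -----------------------------------------------------------

toyMsa <- function(seqs, ids = NULL, dialect = "flush") {
    if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
    ecompass:::newMsa(ids, seqs, dialect = dialect)
}

writeFasta <- function(seqs, ids = names(seqs)) {
    f <- tempfile(fileext = ".fa")
    writeLines(as.vector(rbind(paste0(">", ids), seqs)), f)
    f
}

## --- pair arrays with chosen distinguished placement ----------------------

## Build a pair-array-shaped data.frame of length L whose distinguished
## elements sit at `pos` (array positions, best DC first) and whose k-th
## distinguished element carries distance rank rankPerm[k].
placedArray <- function(pos, rankPerm, L) {
    distinguished <- seq_len(L) %in% pos
    dist <- rep(100, L)
    dist[pos] <- 10 + rankPerm
    data.frame(a = seq_len(L), b = seq_len(L) + L + 10,
               dc = seq(L, 1), dist = dist, distinguished = distinguished)
}

## --- independent ICA oracle ----------------------------------------------

## Statistic recomputed from scratch in R: min over candidate cutoffs of
## hypergeometric tail times one-sided Spearman-concordance tail.
oracleIcaStat <- function(pos, rankPerm, L, D) {
    vals <- vapply(seq_len(D), function(k) {
        ph <- phyper(k - 1, D, L - D, pos[k], lower.tail = FALSE)
        po <- if (k < 3) 1 else {
            rel <- rank(rankPerm[seq_len(k)])
            rho <- 1 - 6 * sum((rel - seq_len(k))^2) / (k * (k^2 - 1))
            pnorm(rho * sqrt(k - 1), lower.tail = FALSE)
        }
        ph * po
    }, numeric(1))
    min(vals)
}

## Exhaustive null of the statistic at small (L, D).
oracleIcaNull <- function(L, D) {
    combs <- utils::combn(L, D)
    perms <- permutationsOf(D)
    out <- numeric(ncol(combs) * nrow(perms))
    idx <- 1L
    for (ci in seq_len(ncol(combs))) {
        for (pi in seq_len(nrow(perms))) {
            out[idx] <- oracleIcaStat(combs[, ci], perms[pi, ], L, D)
            idx <- idx + 1L
        }
    }
    out
}

permutationsOf <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- permutationsOf(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k)
        cbind(k, sub + (sub >= k))))
}

## Vectorized Monte-Carlo estimate of P(T <= tObs) under the null.
oracleIcaMc <- function(L, D, tObs, nmc, seed) {
    set.seed(seed)
    ## D distinct positions per draw via within-row ranks of uniforms
    R1 <- matrix(runif(nmc * L), nmc, L)
    rk <- matrix(0L, nmc, L)
    for (j in seq_len(L)) rk[, j] <- rowSums(R1 < R1[, j]) + 1L
    idx <- which(rk <= D, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), ]
    posM <- matrix(idx[, 2], nrow = nmc, byrow = TRUE)
    ## independent uniform rank permutation
    U2 <- matrix(runif(nmc * D), nmc, D)
    Tm <- matrix(1, nmc, D)
    for (k in seq_len(D)) {
        ph <- phyper(k - 1, D, L - D, posM[, k], lower.tail = FALSE)
        po <- 1
        if (k >= 3) {
            rel <- matrix(0L, nmc, k)
            for (j in seq_len(k))
                rel[, j] <- rowSums(U2[, seq_len(k), drop = FALSE] < U2[, j]) + 1L
            rho <- 1 - 6 * rowSums((rel - matrix(seq_len(k), nmc, k,
                                                 byrow = TRUE))^2) /
                (k * (k^2 - 1))
            po <- pnorm(rho * sqrt(k - 1), lower.tail = FALSE)
        }
        Tm[, k] <- ph * po
    }
    Tmin <- do.call(pmin, as.data.frame(Tm))
    mean(Tmin <= tObs * (1 + 1e-9))
}

## --- structures -----------------------------------------------------------

pdbAtomLine <- function(serial, name, resname, chain, resno, x, y, z,
                        occ = 1.0, altloc = " ", element = NULL) {
    if (is.null(element)) element <- substr(trimws(name), 1, 1)
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, altloc, resname, chain, resno, x, y, z, occ, 0.0,
            element)
}

## Minimal three-residue chain: ALA - GLY - SER, with sidechains placed at
## known coordinates for hand-checkable distances.
writeToyPdb <- function(path = tempfile(fileext = ".pdb")) {
    lines <- c(
        pdbAtomLine(1, " N  ", "ALA", "A", 1, 0, 0, 0),
        pdbAtomLine(2, " CA ", "ALA", "A", 1, 1.5, 0, 0),
        pdbAtomLine(3, " C  ", "ALA", "A", 1, 2.2, 1.2, 0),
        pdbAtomLine(4, " O  ", "ALA", "A", 1, 3.0, 1.2, 1),
        pdbAtomLine(5, " CB ", "ALA", "A", 1, 2.0, -1.4, 0),
        pdbAtomLine(6, " N  ", "GLY", "A", 2, 2.0, 2.4, 0),
        pdbAtomLine(7, " CA ", "GLY", "A", 2, 5.5, 0, 0),
        pdbAtomLine(8, " C  ", "GLY", "A", 2, 6.5, 1, 0),
        pdbAtomLine(9, " O  ", "GLY", "A", 2, 7.5, 1, 1),
        pdbAtomLine(10, " N  ", "SER", "A", 3, 6.3, 2.2, 0),
        pdbAtomLine(11, " CA ", "SER", "A", 3, 9.0, 0, 0),
        pdbAtomLine(12, " C  ", "SER", "A", 3, 10.0, 1.1, 0),
        pdbAtomLine(13, " O  ", "SER", "A", 3, 11.0, 1.1, 1),
        pdbAtomLine(14, " CB ", "SER", "A", 3, 9.5, -1.5, 0),
        pdbAtomLine(15, " OG ", "SER", "A", 3, 8.5, -2.5, 0),
        "END")
    writeLines(lines, path)
    path
}

## Altloc fixture: one CB with two alternate locations (A occ 0.6, B 0.4).
writeAltlocPdb <- function(path = tempfile(fileext = ".pdb")) {
    lines <- c(
        pdbAtomLine(1, " CA ", "ALA", "A", 1, 0, 0, 0),
        pdbAtomLine(2, " CB ", "ALA", "A", 1, 1.0, 1.0, 1.0, occ = 0.6,
                    altloc = "A"),
        pdbAtomLine(3, " CB ", "ALA", "A", 1, 9.0, 9.0, 9.0, occ = 0.4,
                    altloc = "B"),
        pdbAtomLine(4, " CA ", "ALA", "A", 2, 3.8, 0, 0),
        pdbAtomLine(5, " CB ", "ALA", "A", 2, 4.5, 1.0, 0),
        "END")
    writeLines(lines, path)
    path
}

## Straight-line chain structure with given per-residue spacing; sidechain
## is the Calpha itself (glycine-like beads).
beadStructure <- function(id, sequence, spacing = 3.8) {
    n <- nchar(sequence)
    coords <- cbind((seq_len(n) - 1) * spacing, 0, 0)
    newReferenceStructure(id, sequence, coords)
}

## --- small comparison fixture ---------------------------------------------

## A complete two-MSA comparison built from one planted model: gold vs a
## corrupted copy, with `nAnchors` pseudo-structures anchored to distinct
## sampled records. Fits are cached per test session.
localComparisonFixture <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        pm <- makePlantedModel(30, 20, couplingScale = 1.0, seed = 301)
        gold <- sampleMsa(pm, n = 200, seed = 302)
        corrupted <- corruptAlignment(gold, 0.5, maxShift = 3, seed = 303)
        corrupted <- filterNullColumns(corrupted)
        s1 <- frobeniusApc(fitPotts(gold@msa, computeWeights(gold@msa)))
        s2 <- frobeniusApc(fitPotts(corrupted, computeWeights(corrupted)))
        structs <- lapply(1:3, function(k) {
            s <- goldReferenceStructure(gold, record = k)
            s@id <- paste0(s@id, "_r", k)
            s
        })
        cache <<- list(pm = pm, gold = gold, corrupted = corrupted,
                       scores1 = s1, scores2 = s2, structures = structs)
        cache
    }
})
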