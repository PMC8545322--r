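## Mapping structures onto MSA columns and building the comparable ordered
## pair arrays (the ICA inputs).

#' Locate the MSA record matching a structure's chain sequence
#'
#' Scans every record's ungapped sequence for a contiguous window equal in
#' length to the structure sequence with at most `maxMismatch` mismatched
#' positions. Exactly one best match is required.
#'
#' @param structure a [ReferenceStructure].
#' @param msa an [Msa].
#' @param maxMismatch tolerated mismatch fraction (default 0.05).
#' @return A list with `row` (record index) and `offset` (number of record
#'   residues preceding structure position 1), or `NULL` (with a warning)
#'   when no record matches.
#' @export
locateStructureRow <- function(structure, msa, maxMismatch = 0.05) {
    sseq <- strsplit(structure@sequence, "")[[1]]
    n <- length(sseq)
    ung <- ungappedSeqs(msa)
    best <- NULL; bestMm <- Inf; nBest <- 0L
    for (r in seq_along(ung)) {
        u <- strsplit(ung[r], "")[[1]]
        if (length(u) < n) next
        for (off in 0:(length(u) - n)) {
            mm <- sum(u[off + seq_len(n)] != sseq)
            if (mm < bestMm) {
                bestMm <- mm; best <- list(row = r, offset = off); nBest <- 1L
            } else if (mm == bestMm &&
                       !(identical(best$row, r) && identical(best$offset, off))) {
                nBest <- nBest + 1L
            }
        }
    }
    if (is.null(best) || bestMm > maxMismatch * n) {
        warning(sprintf(
            "structure %s: no MSA record matches its chain sequence; skipped",
            structure@id))
        return(NULL)
    }
    if (nBest > 1L)
        stop(sprintf(paste0("structure %s matches several records equally ",
                            "well; supply an explicit structure-to-record ",
                            "mapping"), structure@id))
    best
}

## Residue position -> alignment column for one record: the k-th residue
## (non-null character) of the row sits in the returned column k.
residueColumns <- function(msa, row) {
    chars <- strsplit(msa@seqs[row], "")[[1]]
    which(!grepl(NULL_REGEX, chars))
}

#' Map a structure's residues into the scored columns of two MSAs
#'
#' Combines [locateStructureRow()] with each record's residue-to-column
#' map, restricted to scored columns, and derives the common residue set R
#' (residues mapped to scored columns in both MSAs).
#'
#' @param structure a [ReferenceStructure].
#' @param msa1,msa2 the two [Msa]s.
#' @param rows optional explicit record indices (length 2), overriding the
#'   sequence search.
#' @param maxMismatch passed to [locateStructureRow()].
#' @return A [StructureAlignmentMap], or `NULL` when the structure cannot
#'   be located in one of the MSAs.
#' @export
buildStructureMap <- function(structure, msa1, msa2, rows = NULL,
                              maxMismatch = 0.05) {
    n <- nchar(structure@sequence)
    msas <- list(msa1, msa2)
    rowIdx <- integer(2)
    maps <- vector("list", 2)
    for (k in 1:2) {
        if (!is.null(rows)) {
            loc <- list(row = rows[k], offset = NULL)
            loc$offset <- locateOffsetForRow(structure, msas[[k]], rows[k],
                                             maxMismatch)
            if (is.null(loc$offset)) return(NULL)
        } else {
            loc <- locateStructureRow(structure, msas[[k]], maxMismatch)
            if (is.null(loc)) return(NULL)
        }
        rowIdx[k] <- loc$row
        resCols <- residueColumns(msas[[k]], loc$row)
        cols <- resCols[loc$offset + seq_len(n)]
        ## restrict to scored columns; report indices in scored-column space
        scored <- scoredColumns(msas[[k]])
        idx <- match(cols, scored)
        maps[[k]] <- as.integer(idx)
    }
    rSet <- which(!is.na(maps[[1]]) & !is.na(maps[[2]]))
    new("StructureAlignmentMap", structureId = structure@id,
        rowIndex = rowIdx, residueToColumn = maps, rSet = as.integer(rSet))
}

locateOffsetForRow <- function(structure, msa, row, maxMismatch) {
    sseq <- strsplit(structure@sequence, "")[[1]]
    u <- strsplit(ungappedSeqs(msa)[row], "")[[1]]
    n <- length(sseq)
    if (length(u) < n) return(NULL)
    mms <- vapply(0:(length(u) - n),
                  function(off) sum(u[off + seq_len(n)] != sseq), numeric(1))
    off <- which.min(mms) - 1L
    if (mms[off + 1L] > maxMismatch * n) {
        warning(sprintf("structure %s does not match record %d", structure@id, row))
        return(NULL)
    }
    off
}

#' Build the comparable ordered pair arrays for one structure
#'
#' Candidate pairs are residues `(a, b)` of the common set R with at least
#' `m` intervening residues in the chain (`b - a >= m + 1`). Each pair
#' carries the MSA-specific DC score of its column pair plus the
#' structure's minimum sidechain distance and contact flag; both arrays are
#' sorted by their own DC score descending (ties broken by `(a, b)`
#' lexicographic order), so they hold the same entries with the same L and
#' D and differ only in ordering and scores.
#'
#' @param map a [StructureAlignmentMap].
#' @param scores1,scores2 the two [CouplingScores].
#' @param structure the [ReferenceStructure] the map was built from.
#' @param m minimum number of intervening residues (default 5).
#' @param z contact cutoff in Angstrom (default 4).
#' @return List of two [PairArray]s (`k1`, `k2`), or `NULL` (with a
#'   warning) when the structure yields no usable pairs.
#' @export
buildPairArrays <- function(map, scores1, scores2, structure, m = 5L,
                            z = 4.0) {
    R <- map@rSet
    if (length(R) < 2L) {
        warning(sprintf("structure %s: common residue set too small; unusable",
                        map@structureId))
        return(NULL)
    }
    cand <- allPairs(length(R))
    a <- R[cand[, 1]]; b <- R[cand[, 2]]
    keep <- (b - a) >= m + 1L
    a <- a[keep]; b <- b[keep]
    if (!length(a)) {
        warning(sprintf("structure %s: no residue pairs pass the separation filter",
                        map@structureId))
        return(NULL)
    }
    dist <- structure@minDist[cbind(a, b)]
    usable <- !is.na(dist)
    a <- a[usable]; b <- b[usable]; dist <- dist[usable]
    if (!length(a)) {
        warning(sprintf("structure %s: no residue pairs with resolved distances",
                        map@structureId))
        return(NULL)
    }
    distinguished <- dist <= z
    one <- function(scores, whichMsa, label) {
        cols <- map@residueToColumn[[whichMsa]]
        dc <- dcScores(scores)[cbind(cols[a], cols[b])]
        ord <- order(-dc, a, b)
        entries <- data.frame(a = a, b = b, dc = dc, dist = dist,
                              distinguished = distinguished)[ord, ]
        rownames(entries) <- NULL
        new("PairArray", entries = entries, L = length(a),
            D = as.integer(sum(distinguished)), msaLabel = label,
            structureId = map@structureId)
    }
    list(k1 = one(scores1, 1L, "msa1"), k2 = one(scores2, 2L, "msa2"))
}
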