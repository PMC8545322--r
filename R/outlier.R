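## Distance-matrix discrepancy filtering: flagging reference structures
## likely misaligned within an MSA.

#' Pairwise Calpha distance-matrix discrepancy table
#'
#' For each structure the common residue set holds its residues aligned
#' (in this MSA) to residues of every other structure; by construction it
#' has the same size for all structures. The discrepancy between
#' structures i and j is the mean absolute difference of Calpha distances
#' over all residue pairs of that set (no separation filter), and the
#' per-structure value is the mean over partners.
#'
#' @param structures list of [ReferenceStructure]s.
#' @param maps list of [StructureAlignmentMap]s (same order); the map of
#'   MSA `whichMsa` is used.
#' @param whichMsa 1 or 2: which MSA's alignment to assess.
#' @param msaLabel label recorded in the table.
#' @return A [DeltaDTable] with no exclusions yet.
#' @export
deltaDMatrix <- function(structures, maps, whichMsa = 1L,
                         msaLabel = paste0("msa", whichMsa)) {
    ns <- length(structures)
    if (ns < 2L) stop("need at least two usable structures")
    ids <- vapply(structures, function(s) s@id, character(1))
    ## residue -> scored column maps for the chosen MSA
    colMaps <- lapply(maps, function(m) m@residueToColumn[[whichMsa]])
    ## columns covered by residues of every structure
    colSets <- lapply(colMaps, function(cm) cm[!is.na(cm)])
    common <- Reduce(intersect, colSets)
    if (length(common) < 2L)
        stop(sprintf(paste0("alignment %s is too gappy across the structure ",
                            "set: only %d shared columns"),
                     msaLabel, length(common)))
    common <- sort(common)
    ## residue of each structure sitting in each common column
    resAt <- vapply(colMaps, function(cm) match(common, cm),
                    integer(length(common)))
    disc <- matrix(0, ns, ns)
    for (i in seq_len(ns - 1L)) {
        di <- structures[[i]]@caDist[resAt[, i], resAt[, i]]
        for (j in (i + 1L):ns) {
            dj <- structures[[j]]@caDist[resAt[, j], resAt[, j]]
            v <- mean(abs(di - dj)[upper.tri(di)])
            disc[i, j] <- v; disc[j, i] <- v
        }
    }
    perStructure <- rowSums(disc) / (ns - 1L)
    new("DeltaDTable", msaLabel = msaLabel, structureIds = ids,
        pairDiscrepancy = disc, perStructure = perStructure,
        nShared = length(common), excluded = character(0),
        mean = mean(perStructure),
        sd = stats::sd(perStructure))
}

#' Build a discrepancy table from precomputed per-structure values
#'
#' Convenience constructor for working directly with published or
#' externally computed per-structure discrepancies.
#'
#' @param values named numeric vector of per-structure discrepancies.
#' @param msaLabel label recorded in the table.
#' @return A [DeltaDTable] (pairwise matrix left at zero).
#' @export
deltaDFromValues <- function(values, msaLabel = "msa1") {
    ids <- names(values)
    if (is.null(ids)) ids <- paste0("s", seq_along(values))
    n <- length(values)
    new("DeltaDTable", msaLabel = msaLabel, structureIds = ids,
        pairDiscrepancy = matrix(0, n, n), perStructure = unname(values),
        nShared = 0L, excluded = character(0),
        mean = mean(values), sd = stats::sd(values))
}

#' Iterative outlier exclusion on per-structure discrepancies
#'
#' Repeatedly computes the mean and sample SD (n-1 denominator) of the
#' retained per-structure discrepancies and removes every structure lying
#' at or above `mean + sdMultiplier * SD`, until no removal occurs. The
#' discrepancy values themselves are frozen; only the summary statistics
#' are recomputed. A zero SD (all retained values equal) short-circuits to
#' no removals.
#'
#' @param table a [DeltaDTable].
#' @param sdMultiplier exclusion threshold in SD units (default 2).
#' @return The [DeltaDTable] with `excluded`, `mean` and `sd` updated to
#'   the converged retained set.
#' @export
iterativeExclusion <- function(table, sdMultiplier = 2.0) {
    vals <- table@perStructure
    ids <- table@structureIds
    retained <- rep(TRUE, length(vals))
    if (sum(retained) < 3L)
        stop("need at least three structures to estimate an exclusion SD")
    repeat {
        m <- mean(vals[retained])
        s <- stats::sd(vals[retained])
        if (!is.finite(s) || s == 0) break
        drop <- retained & (vals >= m + sdMultiplier * s)
        if (!any(drop)) break
        retained <- retained & !drop
        if (!any(retained))
            stop("exclusion removed every structure; inspect the alignment")
        if (sum(retained) < 2L) break
    }
    table@excluded <- ids[!retained]
    table@mean <- mean(vals[retained])
    table@sd <- if (sum(retained) > 1L) stats::sd(vals[retained]) else 0
    table
}

#' Greedy selection of sequence-diverse structures
#'
#' Keeps a structure only when its pairwise identity to every already-kept
#' structure does not exceed the cutoff. Identity is computed over the
#' residues the MSA mutually aligns (map of MSA 1 by default); structure
#' pairs with no mutually aligned residues are treated as non-redundant.
#'
#' @param structures list of [ReferenceStructure]s.
#' @param maps matching list of [StructureAlignmentMap]s.
#' @param identityCutoff keep threshold (default 0.65, i.e. structures
#'   sharing at most 65 percent identity).
#' @param whichMsa which MSA's alignment defines mutual residues.
#' @param minRecommended warn when fewer than this many survive
#'   (a comparison is most reliable with at least 10 diverse structures).
#' @return Integer indices of the selected structures.
#' @export
selectDiverseStructures <- function(structures, maps, identityCutoff = 0.65,
                                    whichMsa = 1L, minRecommended = 10L) {
    ns <- length(structures)
    seqs <- lapply(structures, function(s) strsplit(s@sequence, "")[[1]])
    colMaps <- lapply(maps, function(m) m@residueToColumn[[whichMsa]])
    kept <- integer(0)
    for (i in seq_len(ns)) {
        redundant <- FALSE
        for (j in kept) {
            shared <- intersect(colMaps[[i]][!is.na(colMaps[[i]])],
                                colMaps[[j]][!is.na(colMaps[[j]])])
            if (!length(shared)) next
            ri <- match(shared, colMaps[[i]])
            rj <- match(shared, colMaps[[j]])
            ident <- mean(seqs[[i]][ri] == seqs[[j]][rj])
            if (ident > identityCutoff) { redundant <- TRUE; break }
        }
        if (!redundant) kept <- c(kept, i)
    }
    if (length(kept) < minRecommended)
        warning(sprintf(paste0("only %d diverse structures selected; at ",
                               "least %d are recommended for a reliable vote"),
                        length(kept), minRecommended))
    kept
}
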