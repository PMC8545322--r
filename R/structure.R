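## Reference structures: PDB parsing, sidechain contact calls and Calpha
## distance matrices.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read one chain of a PDB file as a reference structure
#'
#' Keeps one entry per residue with a resolved Calpha (residues lacking one
#' are skipped with a warning); for alternate locations the
#' highest-occupancy atom is kept; hydrogens are discarded. Sidechain atom
#' sets are the heavy atoms from Cbeta outward; glycine (and any residue
#' whose sidechain is entirely unresolved) falls back to its Calpha.
#' Residues are numbered by ordinal chain position; author numbering with
#' insertion codes is kept for reporting.
#'
#' @param path PDB coordinate file.
#' @param chain chain identifier.
#' @param id optional structure id (default: file base name + chain).
#' @return A [ReferenceStructure].
#' @export
readStructure <- function(path, chain, id = NULL) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    at <- pdb$atom
    at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
    if (nrow(at) == 0L)
        stop(sprintf("chain '%s' not found in %s", chain, path))
    ## drop hydrogens (and deuterium)
    elesym <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                     trimws(at$elesy), substr(trimws(at$elety), 1, 1))
    at <- at[!toupper(elesym) %in% c("H", "D"), , drop = FALSE]
    ## resolve altlocs: keep highest occupancy per (residue, atom name)
    at$insert[is.na(at$insert)] <- ""
    resKey <- paste(at$resno, at$insert, sep = "@")
    atomKey <- paste(resKey, at$elety, sep = "#")
    o <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(-o, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE][!duplicated(atomKey[ord]), , drop = FALSE]
    at <- at[order(match(paste(at$resno, at$insert, sep = "@"),
                         unique(resKey)), at$elety != "CA"), , drop = FALSE]
    resKey <- paste(at$resno, at$insert, sep = "@")
    residues <- unique(resKey)

    seqChars <- character(0)
    authorNum <- character(0)
    caList <- list(); scList <- list()
    dropped <- 0L
    for (rk in residues) {
        sub <- at[resKey == rk, , drop = FALSE]
        caRow <- which(trimws(sub$elety) == "CA")
        if (!length(caRow)) { dropped <- dropped + 1L; next }
        ca <- as.numeric(sub[caRow[1], c("x", "y", "z")])
        sc <- sub[!trimws(sub$elety) %in% BACKBONE_ATOMS, , drop = FALSE]
        scCoords <- as.matrix(sc[, c("x", "y", "z")])
        if (nrow(scCoords) == 0L)        # glycine or fully disordered
            scCoords <- matrix(ca, nrow = 1)
        aa <- bio3d::aa321(sub$resid[1])
        if (is.na(aa) || aa == "") aa <- "X"
        seqChars <- c(seqChars, aa)
        authorNum <- c(authorNum, paste0(sub$resno[1], trimws(sub$insert[1])))
        caList[[length(caList) + 1L]] <- ca
        scList[[length(scList) + 1L]] <- unname(scCoords)
    }
    if (dropped > 0L)
        warning(sprintf("%s chain %s: skipped %d residue(s) lacking a Calpha",
                        path, chain, dropped))
    if (!length(seqChars))
        stop(sprintf("chain '%s' in %s has no residues with a Calpha", chain, path))
    if (is.null(id))
        id <- paste0(sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path)), chain)
    newReferenceStructure(id, paste(seqChars, collapse = ""),
                          do.call(rbind, caList), scList, authorNum)
}

#' Construct a reference structure from coordinates
#'
#' Builds the distance matrices from explicit Calpha and sidechain
#' coordinates. Used by the PDB reader and by the simulation harness
#' (bead-chain pseudo-structures, whose "sidechain" is the bead itself).
#'
#' @param id structure identifier.
#' @param sequence one-letter residue string.
#' @param caCoords numeric `n x 3` matrix of Calpha coordinates (Angstrom).
#' @param sidechainCoords optional list of `k x 3` matrices, one per
#'   residue; defaults to the Calpha itself for every residue.
#' @param authorNumbering optional character vector of author residue
#'   numbers; defaults to the ordinal positions.
#' @return A [ReferenceStructure].
#' @export
newReferenceStructure <- function(id, sequence, caCoords,
                                  sidechainCoords = NULL,
                                  authorNumbering = NULL) {
    n <- nchar(sequence)
    caCoords <- as.matrix(caCoords)
    if (is.null(sidechainCoords))
        sidechainCoords <- lapply(seq_len(n), function(i)
            caCoords[i, , drop = FALSE])
    if (is.null(authorNumbering)) authorNumbering <- as.character(seq_len(n))
    caDist <- as.matrix(stats::dist(caCoords))
    dimnames(caDist) <- NULL
    atoms <- do.call(rbind, sidechainCoords)
    counts <- vapply(sidechainCoords, nrow, integer(1))
    starts <- cumsum(c(1L, counts[-length(counts)]))
    minDist <- min_pairwise_dist_cpp(atoms, as.integer(starts),
                                     as.integer(counts))
    new("ReferenceStructure", id = id, sequence = sequence,
        authorNumbering = as.character(authorNumbering),
        caCoords = caCoords, sidechainCoords = sidechainCoords,
        caDist = caDist, minDist = minDist)
}

#' Minimum sidechain-atom distance between two residues
#'
#' @param structure a [ReferenceStructure].
#' @param r1,r2 residue ordinal positions.
#' @return Distance in Angstrom (minimum over heavy sidechain atom pairs;
#'   glycine contributes its Calpha).
#' @export
minSidechainDistance <- function(structure, r1, r2) {
    structure@minDist[r1, r2]
}

#' Sidechain contact matrix at a distance cutoff
#'
#' @param structure a [ReferenceStructure].
#' @param z contact cutoff in Angstrom (default 4; a pair at exactly `z`
#'   counts as a contact).
#' @return Logical symmetric matrix: `TRUE` where the minimum sidechain
#'   distance is `<= z`.
#' @export
contactMatrix <- function(structure, z = 4.0) {
    m <- structure@minDist <= z
    diag(m) <- FALSE
    m[is.na(m)] <- FALSE
    m
}

#' Calpha distance matrix
#'
#' @param structure a [ReferenceStructure].
#' @return Symmetric numeric matrix of Calpha distances (Angstrom).
#' @export
caDistanceMatrix <- function(structure) structure@caDist

#' Export a structure's contact or distance matrix as TSV
#'
#' @param structure a [ReferenceStructure].
#' @param path output file.
#' @param what `"contacts"`, `"ca"` or `"sidechain"`.
#' @param z contact cutoff used when `what = "contacts"`.
#' @return `path`, invisibly.
#' @export
exportStructureMatrix <- function(structure, path,
                                  what = c("contacts", "ca", "sidechain"),
                                  z = 4.0) {
    what <- match.arg(what)
    m <- switch(what,
                contacts = contactMatrix(structure, z) * 1L,
                ca = structure@caDist,
                sidechain = structure@minDist)
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    invisible(path)
}
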