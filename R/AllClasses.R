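#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ecompass, .registration = TRUE
NULL

#' Multiple sequence alignment with a scored-column mask
#'
#' Holds a rectangular protein alignment together with a per-column logical
#' mask marking the columns that downstream direct-coupling analysis scores.
#' For match-state dialects (A2M, Stockholm with a reference line) the mask
#' records the match columns; for flush alignments (plain FASTA) it starts
#' all-`TRUE` and is narrowed by [filterNullColumns()].
#'
#' Null characters are `-` and `.`; any letter is a residue. Sequences are
#' stored uppercased; the dialect records which convention produced the mask.
#'
#' @slot ids character vector of unique record identifiers.
#' @slot seqs character vector of aligned sequences, all the same width.
#' @slot columnMask logical vector, one entry per alignment column; `TRUE`
#'   marks a scored column.
#' @slot dialect either `"match_state"` or `"flush"`.
#' @export
setClass("Msa", representation(
    ids = "character",
    seqs = "character",
    columnMask = "logical",
    dialect = "character"
))

setValidity("Msa", function(object) {
    msgs <- character()
    w <- unique(nchar(object@seqs))
    if (length(object@seqs) == 0L)
        msgs <- c(msgs, "Msa must contain at least one record")
    if (length(w) > 1L)
        msgs <- c(msgs, "aligned sequences must all have the same width")
    if (length(object@ids) != length(object@seqs))
        msgs <- c(msgs, "ids and seqs lengths differ")
    if (anyDuplicated(object@ids))
        msgs <- c(msgs, "record identifiers must be unique")
    if (length(w) == 1L && length(object@columnMask) != w)
        msgs <- c(msgs, "columnMask length must equal the alignment width")
    if (!object@dialect %in% c("match_state", "flush"))
        msgs <- c(msgs, "dialect must be 'match_state' or 'flush'")
    if (length(msgs)) msgs else TRUE
})

#' Sequence weights from identity-based clustering
#'
#' Each record's weight is the reciprocal of the number of records (itself
#' included) whose fractional identity over scored columns meets the
#' clustering threshold; `meff` is the effective number of sequences.
#'
#' @slot weights numeric vector, one weight per MSA record, each in (0, 1].
#' @slot meff effective sequence number, `sum(weights)`.
#' @slot threshold identity threshold in (0, 1] used for clustering.
#' @export
setClass("SequenceWeights", representation(
    weights = "numeric",
    meff = "numeric",
    threshold = "numeric"
))

setValidity("SequenceWeights", function(object) {
    msgs <- character()
    if (any(object@weights <= 0 | object@weights > 1 + 1e-12))
        msgs <- c(msgs, "weights must lie in (0, 1]")
    if (abs(object@meff - sum(object@weights)) > 1e-8 * max(1, object@meff))
        msgs <- c(msgs, "meff must equal sum(weights)")
    if (object@threshold <= 0 || object@threshold > 1)
        msgs <- c(msgs, "threshold must lie in (0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Potts model over scored alignment columns
#'
#' A 21-state Markov random field: 20 amino acids plus one catch-all state
#' for gaps and nonstandard residues. Fields are per-column state
#' propensities; couplings are per-column-pair 21 x 21 blocks stored for
#' ordered pairs i < j (the j,i block is the transpose).
#'
#' @slot nCols number of scored columns modelled.
#' @slot nStates alphabet size (21).
#' @slot fields numeric matrix `nStates x nCols`.
#' @slot pairs integer matrix with two columns giving the ordered column
#'   pairs (i < j, 1-based) that carry coupling blocks.
#' @slot couplings numeric array `nStates x nStates x nrow(pairs)`.
#' @slot metadata list of fitting provenance (regularization, convergence,
#'   iterations, weights threshold).
#' @export
setClass("PottsModel", representation(
    nCols = "integer",
    nStates = "integer",
    fields = "matrix",
    pairs = "matrix",
    couplings = "array",
    metadata = "list"
))

setValidity("PottsModel", function(object) {
    msgs <- character()
    q <- object@nStates
    if (!identical(dim(object@fields), c(q, object@nCols)))
        msgs <- c(msgs, "fields must be nStates x nCols")
    if (ncol(object@pairs) != 2L)
        msgs <- c(msgs, "pairs must have two columns")
    if (nrow(object@pairs) > 0L && any(object@pairs[, 1] >= object@pairs[, 2]))
        msgs <- c(msgs, "pairs must be ordered i < j")
    d <- dim(object@couplings)
    if (length(d) != 3L || d[1] != q || d[2] != q || d[3] != nrow(object@pairs))
        msgs <- c(msgs, "couplings must be nStates x nStates x nrow(pairs)")
    if (length(msgs)) msgs else TRUE
})

#' Direct-coupling score matrix for one MSA
#'
#' Symmetric matrix of APC-corrected Frobenius norms over scored-column
#' indices; the diagonal is undefined and stored as `NA`.
#'
#' @slot scores symmetric numeric matrix of DC scores.
#' @slot nCols number of scored columns (matrix dimension).
#' @slot metadata list: reweighting threshold, regularization strength,
#'   source (`"internal"` or `"imported"`).
#' @export
setClass("CouplingScores", representation(
    scores = "matrix",
    nCols = "integer",
    metadata = "list"
))

setValidity("CouplingScores", function(object) {
    msgs <- character()
    s <- object@scores
    if (nrow(s) != object@nCols || ncol(s) != object@nCols)
        msgs <- c(msgs, "scores must be nCols x nCols")
    off <- s; diag(off) <- 0
    if (any(abs(off - t(off)) > 1e-8, na.rm = TRUE))
        msgs <- c(msgs, "scores must be symmetric")
    if (length(msgs)) msgs else TRUE
})

#' Reference structure: one chain's residues, coordinates and distances
#'
#' Residues are indexed by their 1-based ordinal position along the chain
#' (decoupled from author numbering, which is retained for reporting). The
#' sidechain distance between two residues is the minimum over heavy
#' sidechain atoms (Cbeta outward; glycine falls back to Calpha).
#'
#' @slot id structure identifier, e.g. PDB id plus chain.
#' @slot sequence one-letter residue sequence along the chain.
#' @slot authorNumbering character vector of author residue numbers
#'   (with insertion codes) for reporting.
#' @slot caCoords numeric matrix `n x 3` of Calpha coordinates (Angstrom).
#' @slot sidechainCoords list of numeric matrices (`k x 3`), one per
#'   residue, holding heavy sidechain atom coordinates.
#' @slot caDist symmetric Calpha distance matrix (Angstrom).
#' @slot minDist symmetric minimum sidechain-atom distance matrix (Angstrom).
#' @export
setClass("ReferenceStructure", representation(
    id = "character",
    sequence = "character",
    authorNumbering = "character",
    caCoords = "matrix",
    sidechainCoords = "list",
    caDist = "matrix",
    minDist = "matrix"
))

setValidity("ReferenceStructure", function(object) {
    msgs <- character()
    n <- nchar(object@sequence)
    if (nrow(object@caCoords) != n || ncol(object@caCoords) != 3L)
        msgs <- c(msgs, "caCoords must be n x 3")
    if (length(object@sidechainCoords) != n)
        msgs <- c(msgs, "sidechainCoords must have one entry per residue")
    for (nm in c("caDist", "minDist")) {
        m <- slot(object, nm)
        if (!all(dim(m) == c(n, n))) {
            msgs <- c(msgs, sprintf("%s must be n x n", nm))
            next
        }
        if (any(m < -1e-9, na.rm = TRUE) || max(abs(diag(m)), na.rm = TRUE) > 1e-9 ||
            max(abs(m - t(m)), na.rm = TRUE) > 1e-6)
            msgs <- c(msgs, sprintf("%s must be symmetric, non-negative, zero-diagonal", nm))
    }
    if (length(msgs)) msgs else TRUE
})

#' Residue-to-column maps of a structure into two MSAs
#'
#' @slot structureId identifier of the mapped structure.
#' @slot rowIndex integer vector of length 2: record index in each MSA.
#' @slot residueToColumn list of two integer vectors; entry `k` maps the
#'   structure's residue position `k` to a scored-column index (NA when
#'   unmapped).
#' @slot rSet sorted integer vector of residue positions mapped to scored
#'   columns in both MSAs.
#' @export
setClass("StructureAlignmentMap", representation(
    structureId = "character",
    rowIndex = "integer",
    residueToColumn = "list",
    rSet = "integer"
))

setValidity("StructureAlignmentMap", function(object) {
    msgs <- character()
    if (length(object@residueToColumn) != 2L)
        msgs <- c(msgs, "residueToColumn must hold one map per MSA")
    for (m in object@residueToColumn) {
        mm <- m[!is.na(m)]
        if (anyDuplicated(mm))
            msgs <- c(msgs, "residue-to-column maps must be injective")
    }
    for (m in object@residueToColumn)
        if (any(is.na(m[object@rSet])))
            msgs <- c(msgs, "rSet must be mapped in both MSAs")
    if (length(msgs)) msgs else TRUE
})

#' Ordered array of DC-scored residue pairs for one structure and one MSA
#'
#' The comparable subset of an MSA's DC scores restricted to residue pairs
#' of the common set R with at least `m` intervening residues, sorted by DC
#' score descending. Distinguished entries are contacts (minimum sidechain
#' distance within the cutoff).
#'
#' @slot entries data.frame with columns `a`, `b` (residue positions,
#'   a < b), `dc` (DC score), `dist` (Angstrom), `distinguished` (logical).
#' @slot L number of entries.
#' @slot D number of distinguished entries.
#' @slot msaLabel which MSA the DC scores came from.
#' @slot structureId source structure.
#' @export
setClass("PairArray", representation(
    entries = "data.frame",
    L = "integer",
    D = "integer",
    msaLabel = "character",
    structureId = "character"
))

setValidity("PairArray", function(object) {
    msgs <- character()
    e <- object@entries
    need <- c("a", "b", "dc", "dist", "distinguished")
    if (!all(need %in% names(e)))
        msgs <- c(msgs, "entries must have columns a, b, dc, dist, distinguished")
    else {
        if (nrow(e) != object@L) msgs <- c(msgs, "L must equal nrow(entries)")
        if (sum(e$distinguished) != object@D)
            msgs <- c(msgs, "D must equal the number of distinguished entries")
        if (is.unsorted(rev(e$dc)))
            msgs <- c(msgs, "entries must be sorted by dc descending")
        if (any(e$a >= e$b)) msgs <- c(msgs, "pairs must satisfy a < b")
    }
    if (length(msgs)) msgs else TRUE
})

#' Initial Cluster Analysis result
#'
#' @slot sScore the S-score, `-log10(P)`.
#' @slot pValue attained significance of the congruence statistic.
#' @slot bestCutoff initial-segment length X at the optimum.
#' @slot dAtCutoff number of distinguished elements within the optimal
#'   segment.
#' @slot L,D array size and number of distinguished elements.
#' @slot components numeric vector `c(enrichment_p, ordering_p)` at the
#'   optimal cutoff.
#' @slot method `"exact"` (enumerated null) or `"bonferroni"` (Fisher
#'   combination with Bonferroni correction over candidate cutoffs).
#' @export
setClass("IcaResult", representation(
    sScore = "numeric",
    pValue = "numeric",
    bestCutoff = "integer",
    dAtCutoff = "integer",
    L = "integer",
    D = "integer",
    components = "numeric",
    method = "character"
))

setValidity("IcaResult", function(object) {
    msgs <- character()
    if (object@pValue <= 0 || object@pValue > 1)
        msgs <- c(msgs, "pValue must lie in (0, 1]")
    if (abs(object@sScore + log10(object@pValue)) > 1e-8 * max(1, object@sScore))
        msgs <- c(msgs, "sScore must equal -log10(pValue)")
    if (object@dAtCutoff > min(object@bestCutoff, object@D))
        msgs <- c(msgs, "dAtCutoff cannot exceed min(bestCutoff, D)")
    if (length(msgs)) msgs else TRUE
})

#' Distance-matrix discrepancy table for one MSA
#'
#' @slot msaLabel which MSA the table was computed from.
#' @slot structureIds structure identifiers (row/col order of the matrix).
#' @slot pairDiscrepancy symmetric matrix of pairwise discrepancies
#'   (mean absolute Calpha distance difference, Angstrom).
#' @slot perStructure per-structure discrepancy (mean over partners).
#' @slot nShared size of the common residue set underlying the table.
#' @slot excluded character vector of excluded structure ids.
#' @slot mean,sd summary of the *retained* per-structure values.
#' @export
setClass("DeltaDTable", representation(
    msaLabel = "character",
    structureIds = "character",
    pairDiscrepancy = "matrix",
    perStructure = "numeric",
    nShared = "integer",
    excluded = "character",
    mean = "numeric",
    sd = "numeric"
))

setValidity("DeltaDTable", function(object) {
    msgs <- character()
    m <- object@pairDiscrepancy
    n <- length(object@structureIds)
    if (!all(dim(m) == c(n, n)))
        msgs <- c(msgs, "pairDiscrepancy must be square over structureIds")
    else if (any(m < -1e-9, na.rm = TRUE) || max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
        msgs <- c(msgs, "pairDiscrepancy must be symmetric and non-negative")
    if (length(object@perStructure) != n)
        msgs <- c(msgs, "perStructure must have one value per structure")
    if (!all(object@excluded %in% object@structureIds))
        msgs <- c(msgs, "excluded ids must be a subset of structureIds")
    if (length(msgs)) msgs else TRUE
})

#' Full two-MSA comparison report
#'
#' @slot verdicts data.frame, one row per reference structure: S-scores,
#'   delta S, per-MSA distance discrepancies, counts, exclusion flags.
#' @slot withExclusion,withoutExclusion summary lists: `n1`, `n2`,
#'   `deltaSMean`, `deltaSSd`, `binomialP`, `negLog10P`, `deltaDMean1`,
#'   `deltaDMean2`, `nRetained`, `flags`.
#' @slot config the configuration the run used.
#' @slot deltaD list of the two [DeltaDTable]s.
#' @export
setClass("ComparisonReport", representation(
    verdicts = "data.frame",
    withExclusion = "list",
    withoutExclusion = "list",
    config = "list",
    deltaD = "list"
))

#' Potts model with a planted contact graph and pseudo-structure
#'
#' @slot potts the generating [PottsModel]; couplings are nonzero only on
#'   the planted contact pairs.
#' @slot contactGraph integer matrix (two columns) of planted column pairs.
#' @slot pseudoStructure a bead-chain [ReferenceStructure] realizing the
#'   contact graph at 8 Angstrom or less.
#' @slot seed integer seed the generator used.
#' @export
setClass("PlantedModel", representation(
    potts = "PottsModel",
    contactGraph = "matrix",
    pseudoStructure = "ReferenceStructure",
    seed = "integer"
))

#' Gold-standard sampled alignment paired with its generating model
#'
#' @slot msa gap-free sampled [Msa] whose columns are the model's columns.
#' @slot model the generating [PlantedModel].
#' @export
setClass("GoldStandard", representation(
    msa = "Msa",
    model = "PlantedModel"
))

setValidity("GoldStandard", function(object) {
    if (any(grepl("[-.]", object@msa@seqs)))
        "gold-standard alignments must be gap-free" else TRUE
})
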