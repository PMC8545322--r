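#' Accessors for ecompass classes
#'
#' Small read-only accessors so client code never touches slots directly.
#'
#' @param x an ecompass object.
#' @return The requested component.
#' @name accessors
NULL

#' @describeIn accessors record identifiers of an [Msa].
#' @export
msaIds <- function(x) { stopifnot(is(x, "Msa")); x@ids }

#' @describeIn accessors aligned sequences (named character vector).
#' @export
msaSeqs <- function(x) {
    stopifnot(is(x, "Msa"))
    stats::setNames(x@seqs, x@ids)
}

#' @describeIn accessors logical scored-column mask.
#' @export
columnMask <- function(x) { stopifnot(is(x, "Msa")); x@columnMask }

#' @describeIn accessors indices of scored columns.
#' @export
scoredColumns <- function(x) which(columnMask(x))

#' @describeIn accessors alignment width.
#' @export
msaWidth <- function(x) { stopifnot(is(x, "Msa")); nchar(x@seqs[1]) }

#' @describeIn accessors number of records.
#' @export
msaLength <- function(x) { stopifnot(is(x, "Msa")); length(x@seqs) }

#' @describeIn accessors the symmetric DC score matrix of a
#'   [CouplingScores] object.
#' @export
dcScores <- function(x) { stopifnot(is(x, "CouplingScores")); x@scores }

#' @describeIn accessors per-record weights of a [SequenceWeights].
#' @export
seqWeights <- function(x) { stopifnot(is(x, "SequenceWeights")); x@weights }

#' @describeIn accessors effective sequence number.
#' @export
meff <- function(x) { stopifnot(is(x, "SequenceWeights")); x@meff }

#' @describeIn accessors S-score of an [IcaResult].
#' @export
sScore <- function(x) { stopifnot(is(x, "IcaResult")); x@sScore }

#' @describeIn accessors entries of a [PairArray] as a data.frame.
#' @export
pairEntries <- function(x) { stopifnot(is(x, "PairArray")); x@entries }

#' @describeIn accessors per-structure verdicts of a [ComparisonReport].
#' @export
verdicts <- function(x) { stopifnot(is(x, "ComparisonReport")); x@verdicts }

#' @describeIn accessors one summary block (`"with"` or `"without"`
#'   exclusion) of a [ComparisonReport].
#' @param block which summary block to return.
#' @export
comparisonSummary <- function(x, block = c("with", "without")) {
    stopifnot(is(x, "ComparisonReport"))
    block <- match.arg(block)
    if (block == "with") x@withExclusion else x@withoutExclusion
}

setMethod("show", "Msa", function(object) {
    cat(sprintf("Msa: %d records x %d columns (%d scored), dialect '%s'\n",
                msaLength(object), msaWidth(object),
                sum(object@columnMask), object@dialect))
})

setMethod("show", "CouplingScores", function(object) {
    cat(sprintf("CouplingScores: %d x %d DC scores (source: %s)\n",
                object@nCols, object@nCols,
                if (is.null(object@metadata$source)) "?" else object@metadata$source))
})

setMethod("show", "PottsModel", function(object) {
    cat(sprintf("PottsModel: %d columns, %d states, %d coupling blocks\n",
                object@nCols, object@nStates, nrow(object@pairs)))
})

setMethod("show", "ReferenceStructure", function(object) {
    cat(sprintf("ReferenceStructure %s: %d residues\n",
                object@id, nchar(object@sequence)))
})

setMethod("show", "PairArray", function(object) {
    cat(sprintf("PairArray [%s / %s]: L = %d, D = %d\n",
                object@structureId, object@msaLabel, object@L, object@D))
})

setMethod("show", "IcaResult", function(object) {
    cat(sprintf("IcaResult: S = %.2f (P = %.3g, X = %d, d = %d, L = %d, D = %d, %s)\n",
                object@sScore, object@pValue, object@bestCutoff,
                object@dAtCutoff, object@L, object@D, object@method))
})

setMethod("show", "DeltaDTable", function(object) {
    cat(sprintf("DeltaDTable [%s]: %d structures, %d excluded, mean %.2f A, SD %.2f A\n",
                object@msaLabel, length(object@structureIds),
                length(object@excluded), object@mean, object@sd))
})

setMethod("show", "ComparisonReport", function(object) {
    w <- object@withExclusion; wo <- object@withoutExclusion
    cat("Two-MSA comparison report\n")
    cat(sprintf("  structures: %d usable (%d after exclusion)\n",
                wo$nRetained, w$nRetained))
    fmt <- function(b, label)
        cat(sprintf("  %-18s n1 = %d, n2 = %d, dS mean = %.1f (SD %.1f), -log10 P = %.1f\n",
                    label, b$n1, b$n2, b$deltaSMean, b$deltaSSd, b$negLog10P))
    fmt(w, "with exclusion:")
    fmt(wo, "without exclusion:")
    cat("  note: structure votes are not fully independent; binomial P-values\n")
    cat("  should be discounted to some extent.\n")
})

setMethod("show", "PlantedModel", function(object) {
    cat(sprintf("PlantedModel: %d columns, %d planted contacts, seed %d\n",
                object@potts@nCols, nrow(object@contactGraph), object@seed))
})

setMethod("show", "GoldStandard", function(object) {
    cat(sprintf("GoldStandard: %d sampled sequences x %d columns\n",
                msaLength(object@msa), msaWidth(object@msa)))
})
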