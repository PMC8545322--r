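## MSA reading/writing, scored-column masks, redundancy purging.

NULL_CHARS <- c("-", ".")
NULL_REGEX <- "[-.]"

newMsa <- function(ids, seqs, columnMask = NULL, dialect = "flush") {
    seqs <- toupper(as.character(seqs))
    seqs <- gsub(".", "-", seqs, fixed = TRUE)
    if (is.null(columnMask)) columnMask <- rep(TRUE, nchar(seqs[1]))
    new("Msa", ids = as.character(ids), seqs = seqs,
        columnMask = columnMask, dialect = dialect)
}

#' Read a multiple sequence alignment
#'
#' Supports plain aligned FASTA (flush dialect: every column initially
#' scored), A2M (match columns are those containing uppercase residues or
#' `-`; lowercase/`.` insert columns are left unscored) and Stockholm
#' (when a `#=GC RF` reference line is present, its non-gap positions mark
#' the scored columns).
#'
#' @param path path to the alignment file.
#' @param format one of `"fasta"`, `"a2m"`, `"stockholm"`.
#' @return An [Msa]. Sequences are uppercased and `.` normalized to `-`;
#'   the dialect and scored-column mask record the format semantics.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "AC-D", ">b", "ACXD"), f)
#' readMsa(f, "fasta")
#' @export
readMsa <- function(path, format = c("fasta", "a2m", "stockholm")) {
    format <- match.arg(format)
    if (format %in% c("fasta", "a2m")) {
        set <- Biostrings::readBStringSet(path)
        if (length(set) == 0L) stop("empty alignment file: ", path)
        ids <- sub("\\s.*$", "", names(set))
        seqs <- as.character(set)
        rf <- NULL
    } else {
        parsed <- readStockholm(path)
        ids <- parsed$ids; seqs <- parsed$seqs; rf <- parsed$rf
    }
    w <- nchar(seqs)
    if (length(unique(w)) > 1L) {
        bad <- ids[which(w != w[1])[1]]
        stop(sprintf("ragged alignment: record '%s' has width %d, expected %d",
                     bad, nchar(seqs[ids == bad][1]), w[1]))
    }
    if (anyDuplicated(ids))
        ids <- make.unique(ids, sep = "_dup")
    mask <- NULL
    dialect <- "flush"
    if (format == "a2m") {
        chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
        ins <- apply(chars, 2, function(cc) all(grepl("[a-z.]", cc)))
        mask <- !ins
        dialect <- "match_state"
    } else if (format == "stockholm" && !is.null(rf)) {
        mask <- !grepl(NULL_REGEX, strsplit(rf, "")[[1]]) &
            strsplit(rf, "")[[1]] != "~"
        dialect <- "match_state"
    }
    newMsa(ids, seqs, mask, dialect)
}

## Minimal Stockholm 1.0 reader: sequence lines plus the #=GC RF track.
readStockholm <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines)) stop("empty alignment file: ", path)
    seqs <- list(); order <- character(); rf <- ""
    for (ln in lines) {
        if (grepl("^\\s*$", ln) || identical(ln, "//")) next
        if (startsWith(ln, "#")) {
            if (grepl("^#=GC\\s+RF\\s+", ln))
                rf <- paste0(rf, sub("^#=GC\\s+RF\\s+", "", ln))
            next
        }
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(parts) < 2L) stop("malformed Stockholm line: ", ln)
        id <- parts[1]
        if (is.null(seqs[[id]])) { seqs[[id]] <- ""; order <- c(order, id) }
        seqs[[id]] <- paste0(seqs[[id]], parts[2])
    }
    if (!length(order)) stop("no sequences found in Stockholm file: ", path)
    list(ids = order, seqs = unlist(seqs[order], use.names = FALSE),
         rf = if (nzchar(rf)) rf else NULL)
}

#' Write an alignment (and optionally its column mask)
#'
#' @param msa an [Msa].
#' @param path output file.
#' @param format `"fasta"` or `"stockholm"` (the mask is emitted as a
#'   `#=GC RF` line for Stockholm).
#' @param maskPath optional path for a per-column 0/1 text track of the
#'   scored-column mask.
#' @return `path`, invisibly.
#' @export
writeMsa <- function(msa, path, format = c("fasta", "stockholm"),
                     maskPath = NULL) {
    format <- match.arg(format)
    if (format == "fasta") {
        set <- Biostrings::BStringSet(stats::setNames(msa@seqs, msa@ids))
        Biostrings::writeXStringSet(set, path)
    } else {
        rf <- paste(ifelse(msa@columnMask, "x", "."), collapse = "")
        idw <- max(nchar(msa@ids), nchar("#=GC RF"))
        body <- sprintf("%-*s %s", idw, msa@ids, msa@seqs)
        writeLines(c("# STOCKHOLM 1.0", body,
                     sprintf("%-*s %s", idw, "#=GC RF", rf), "//"), path)
    }
    if (!is.null(maskPath))
        writeLines(paste(as.integer(msa@columnMask), collapse = " "), maskPath)
    invisible(path)
}

#' Mask columns dominated by null characters
#'
#' For flush alignments, marks as unscored every column whose fraction of
#' null characters (`-` or `.`) strictly exceeds `maxNullFraction`. The
#' sequence text is untouched; only the mask changes. Match-state
#' alignments keep their existing mask.
#'
#' @param msa an [Msa].
#' @param maxNullFraction highest tolerated null fraction (default 0.5:
#'   columns with more than 50 percent nulls are dropped from scoring).
#' @return The [Msa] with an updated `columnMask`.
#' @export
filterNullColumns <- function(msa, maxNullFraction = 0.5) {
    if (msa@dialect != "flush") return(msa)
    chars <- do.call(rbind, strsplit(msa@seqs, "", fixed = TRUE))
    nullFrac <- colMeans(matrix(grepl(NULL_REGEX, chars), nrow = nrow(chars)))
    msa@columnMask <- msa@columnMask & (nullFrac <= maxNullFraction)
    validObject(msa)
    msa
}

## Integer state matrix over the scored columns: 1..20 amino acids in
## AA_ORDER, 21 for gap and any nonstandard letter.
AA_ORDER <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

msaStateMatrix <- function(msa) {
    cols <- scoredColumns(msa)
    chars <- do.call(rbind, strsplit(msa@seqs, "", fixed = TRUE))[, cols,
                                                                 drop = FALSE]
    m <- match(chars, AA_ORDER)
    m[is.na(m)] <- 21L
    matrix(as.integer(m), nrow = msaLength(msa))
}

## Pairwise identity between two aligned rows over scored columns,
## counting only positions where both rows carry residues.
pairIdentityResidues <- function(x, y) {
    both <- !grepl(NULL_REGEX, x) & !grepl(NULL_REGEX, y)
    n <- sum(both)
    if (n == 0L) return(NA_real_)
    sum(x[both] == y[both]) / n
}

#' Remove near-duplicate records
#'
#' Greedy scan in file order: a record is dropped when its identity to any
#' already-kept record reaches the cutoff. Identity is computed over scored
#' columns where both records carry residues; the denominator is the count
#' of such positions, and records with zero comparable positions are kept.
#'
#' @param msa an [Msa].
#' @param identityCutoff drop threshold as a fraction (default 0.95, i.e.
#'   all but one among records sharing at least 95 percent identity).
#' @return The dereplicated [Msa].
#' @export
purgeRedundancy <- function(msa, identityCutoff = 0.95) {
    cols <- scoredColumns(msa)
    chars <- do.call(rbind, strsplit(msa@seqs, "", fixed = TRUE))[, cols,
                                                                 drop = FALSE]
    n <- nrow(chars)
    keep <- logical(n)
    keptIdx <- integer(0)
    for (i in seq_len(n)) {
        dup <- FALSE
        for (j in keptIdx) {
            id <- pairIdentityResidues(chars[j, ], chars[i, ])
            if (!is.na(id) && id >= identityCutoff) { dup <- TRUE; break }
        }
        if (!dup) { keep[i] <- TRUE; keptIdx <- c(keptIdx, i) }
    }
    newMsaSubset(msa, which(keep))
}

newMsaSubset <- function(msa, idx) {
    new("Msa", ids = msa@ids[idx], seqs = msa@seqs[idx],
        columnMask = msa@columnMask, dialect = msa@dialect)
}

## Ungapped sequence text per record (used for structure location and
## sequence-set intersection between two MSAs).
ungappedSeqs <- function(msa) gsub(NULL_REGEX, "", msa@seqs)
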