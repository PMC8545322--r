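## Orchestration of the full two-MSA comparison: per-structure scores,
## outlier handling, summaries and the binomial vote.

#' Two-tailed equiprobable binomial vote P-value
#'
#' With `n = n1 + n2` votes and `k = max(n1, n2)` for the winner,
#' `P = min(1, 2 * sum_{j >= k} C(n, j) / 2^n)`.
#'
#' @param n1,n2 structure counts favoring each MSA.
#' @return The two-tailed P-value.
#' @export
twoTailedBinomialP <- function(n1, n2) {
    exp(-log(10) * negLog10BinomialP(n1, n2))
}

#' -log10 of the two-tailed binomial vote P-value
#'
#' Computed in log space so large unanimous votes keep full precision.
#'
#' @param n1,n2 structure counts favoring each MSA.
#' @return `-log10` of the capped two-tailed P-value.
#' @export
negLog10BinomialP <- function(n1, n2) {
    if (n1 < 0 || n2 < 0 || n1 + n2 < 1)
        stop("binomial vote needs at least one nonzero count")
    n <- n1 + n2
    k <- max(n1, n2)
    logP <- log(2) + stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE,
                                   log.p = TRUE)
    -min(0, logP) / log(10)
}

#' Summarize per-structure verdicts into one report block
#'
#' @param verdicts data.frame with columns `deltaS`, `deltaD1`, `deltaD2`,
#'   `excluded` (logical), `usable` (logical).
#' @param useExclusion drop excluded structures before summarizing?
#' @return List: `n1`, `n2`, `deltaSMean`, `deltaSSd`, `binomialP`,
#'   `negLog10P`, `deltaDMean1`, `deltaDMean2`, `nRetained`, `flags`.
#' @export
summarizeVerdicts <- function(verdicts, useExclusion = TRUE) {
    keep <- verdicts$usable
    if (useExclusion) keep <- keep & !verdicts$excluded
    if (!any(keep)) stop("no structures retained for summary")
    ds <- verdicts$deltaS[keep]
    flags <- character(0)
    n1 <- sum(ds > 0); n2 <- sum(ds < 0)
    if (n1 + n2 == 0L) {
        p <- 1; flags <- c(flags, "no vote")
    } else p <- twoTailedBinomialP(n1, n2)
    sdDs <- if (length(ds) > 1L) stats::sd(ds) else {
        flags <- c(flags, "single structure: SD undefined, reported as 0")
        0
    }
    list(n1 = n1, n2 = n2,
         deltaSMean = mean(ds), deltaSSd = sdDs,
         binomialP = p,
         negLog10P = if (n1 + n2 > 0L) negLog10BinomialP(n1, n2) else 0,
         deltaDMean1 = mean(verdicts$deltaD1[keep], na.rm = TRUE),
         deltaDMean2 = mean(verdicts$deltaD2[keep], na.rm = TRUE),
         nRetained = sum(keep), flags = flags)
}

#' Compare two MSAs of the same protein set against reference structures
#'
#' Runs the full pipeline: scored-column masks, sequence reweighting and
#' pseudo-likelihood DCA per MSA (unless precomputed scores are supplied),
#' per-structure comparable pair arrays and S-scores, per-MSA
#' distance-discrepancy outlier detection, and the with/without-exclusion
#' summaries with the binomial vote. Structures flagged in either MSA are
#' excluded from both (union rule); exclusion never consults the S-scores.
#'
#' @param msa1,msa2 the two [Msa]s (same sequence set; a mismatch leaves
#'   the shared subset with a warning).
#' @param structures list of [ReferenceStructure]s.
#' @param config a configuration list from [ecompassConfig()].
#' @param scores1,scores2 optional precomputed [CouplingScores] (skips the
#'   internal DCA fit for that MSA).
#' @param structureRows optional 2-column integer matrix (one row per
#'   structure) of explicit record indices in each MSA.
#' @param subgroups optional character vector of per-structure subgroup
#'   labels passed through to the verdict table.
#' @return A [ComparisonReport].
#' @export
compareMsas <- function(msa1, msa2, structures, config = ecompassConfig(),
                        scores1 = NULL, scores2 = NULL,
                        structureRows = NULL, subgroups = NULL) {
    shared <- intersectSequenceSets(msa1, msa2)
    msa1 <- shared$msa1; msa2 <- shared$msa2
    msa1 <- filterNullColumns(msa1, config$nullColumnFraction)
    msa2 <- filterNullColumns(msa2, config$nullColumnFraction)

    if (is.null(scores1)) scores1 <- msaCouplingScores(msa1, config)
    if (is.null(scores2)) scores2 <- msaCouplingScores(msa2, config)
    checkScoreDims(scores1, msa1, "msa1")
    checkScoreDims(scores2, msa2, "msa2")

    ns <- length(structures)
    if (ns < 2L) stop("need at least two reference structures")
    if (ns < 10L)
        warning("fewer than 10 reference structures; the binomial vote will have little power")

    maps <- vector("list", ns)
    arrays <- vector("list", ns)
    for (i in seq_len(ns)) {
        rows <- if (!is.null(structureRows)) structureRows[i, ] else NULL
        mp <- buildStructureMap(structures[[i]], msa1, msa2, rows = rows)
        maps[[i]] <- mp
        if (is.null(mp)) next
        arrays[[i]] <- buildPairArrays(mp, scores1, scores2, structures[[i]],
                                       m = config$minSeparation, z = config$z)
    }
    usable <- !vapply(arrays, is.null, logical(1))
    if (sum(usable) < 2L) stop("fewer than two usable reference structures")

    ids <- vapply(structures, function(s) s@id, character(1))
    s1 <- s2 <- ds <- rep(NA_real_, ns)
    Lv <- Dv <- rep(NA_integer_, ns)
    for (i in which(usable)) {
        r1 <- icaScore(arrays[[i]]$k1)
        r2 <- icaScore(arrays[[i]]$k2)
        s1[i] <- sScore(r1); s2[i] <- sScore(r2)
        ds[i] <- deltaS(r1, r2)
        Lv[i] <- r1@L; Dv[i] <- r1@D
    }

    ## distance-discrepancy outlier detection, independently per MSA
    uIdx <- which(usable)
    dd1 <- deltaDMatrix(structures[uIdx], maps[uIdx], whichMsa = 1L,
                        msaLabel = "msa1")
    dd2 <- deltaDMatrix(structures[uIdx], maps[uIdx], whichMsa = 2L,
                        msaLabel = "msa2")
    if (length(uIdx) >= 3L) {
        dd1 <- iterativeExclusion(dd1, config$sdMultiplier)
        dd2 <- iterativeExclusion(dd2, config$sdMultiplier)
    } else {
        warning("fewer than three usable structures; outlier exclusion skipped")
    }
    excludedIds <- union(dd1@excluded, dd2@excluded)

    deltaD1 <- deltaD2 <- rep(NA_real_, ns)
    deltaD1[uIdx] <- dd1@perStructure
    deltaD2[uIdx] <- dd2@perStructure
    excluded <- ids %in% excludedIds & usable
    reason <- rep(NA_character_, ns)
    reason[!usable] <- "unusable"
    reason[ids %in% dd1@excluded] <- "delta_d_msa1"
    reason[ids %in% setdiff(dd2@excluded, dd1@excluded)] <- "delta_d_msa2"

    verdictDf <- data.frame(
        structure = ids, s1 = s1, s2 = s2, deltaS = ds,
        deltaD1 = deltaD1, deltaD2 = deltaD2,
        sharedCols = ifelse(usable,
                            vapply(maps, function(m)
                                if (is.null(m)) NA_integer_
                                else length(m@rSet), integer(1)), NA_integer_),
        D = Dv, L = Lv,
        usable = usable, excluded = excluded, reason = reason,
        stringsAsFactors = FALSE)
    if (!is.null(subgroups)) verdictDf$subgroup <- subgroups

    new("ComparisonReport",
        verdicts = verdictDf,
        withExclusion = summarizeVerdicts(verdictDf, TRUE),
        withoutExclusion = summarizeVerdicts(verdictDf, FALSE),
        config = config,
        deltaD = list(msa1 = dd1, msa2 = dd2))
}

msaCouplingScores <- function(msa, config) {
    w <- computeWeights(msa, config$reweightThreshold)
    model <- fitPotts(msa, w, regStrength = config$regStrength,
                      maxIter = config$maxIter, gradTol = config$gradTol)
    frobeniusApc(model)
}

checkScoreDims <- function(scores, msa, label) {
    if (scores@nCols != sum(columnMask(msa)))
        stop(sprintf("%s: coupling scores have %d columns but the MSA has %d scored columns",
                     label, scores@nCols, sum(columnMask(msa))))
}

## Intersect the two MSAs on ungapped sequence text (multiset semantics:
## duplicated sequences are matched greedily in file order).
intersectSequenceSets <- function(msa1, msa2) {
    u1 <- ungappedSeqs(msa1); u2 <- ungappedSeqs(msa2)
    if (length(u1) == length(u2) && identical(sort(u1), sort(u2)))
        return(list(msa1 = msa1, msa2 = msa2))
    pool2 <- u2
    take1 <- integer(0); take2 <- integer(0)
    for (i in seq_along(u1)) {
        j <- match(u1[i], pool2)
        if (!is.na(j)) {
            take1 <- c(take1, i); take2 <- c(take2, j)
            pool2[j] <- NA_character_
        }
    }
    if (!length(take1))
        stop("the two MSAs share no sequences")
    warning(sprintf(paste0("MSAs do not hold the same sequence set ",
                           "(%d vs %d records, %d shared); the shared ",
                           "subset is used. Differing records: %s"),
                    length(u1), length(u2), length(take1),
                    paste(utils::head(c(msaIds(msa1)[-take1],
                                        msaIds(msa2)[-take2]), 5),
                          collapse = ", ")))
    list(msa1 = newMsaSubset(msa1, take1), msa2 = newMsaSubset(msa2, take2))
}

#' Write a comparison report to TSV and JSON files
#'
#' Emits `<prefix>.verdicts.tsv` (one row per structure),
#' `<prefix>.summary.tsv` (the two summary blocks) and
#' `<prefix>.report.json` (everything, config included).
#'
#' @param report a [ComparisonReport].
#' @param prefix output path prefix.
#' @return The three paths, invisibly.
#' @export
writeReport <- function(report, prefix) {
    vp <- paste0(prefix, ".verdicts.tsv")
    sp <- paste0(prefix, ".summary.tsv")
    jp <- paste0(prefix, ".report.json")
    utils::write.table(verdicts(report), vp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    blocks <- list(with_exclusion = report@withExclusion,
                   without_exclusion = report@withoutExclusion)
    sdf <- do.call(rbind, lapply(names(blocks), function(nm) {
        b <- blocks[[nm]]
        data.frame(block = nm, n1 = b$n1, n2 = b$n2,
                   delta_s_mean = round(b$deltaSMean, 1),
                   delta_s_sd = round(b$deltaSSd, 1),
                   neg_log10_p = round(b$negLog10P, 1),
                   delta_d_mean_msa1 = round(b$deltaDMean1, 2),
                   delta_d_mean_msa2 = round(b$deltaDMean2, 2),
                   n_retained = b$nRetained)
    }))
    utils::write.table(sdf, sp, sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
        list(verdicts = verdicts(report),
             with_exclusion = report@withExclusion,
             without_exclusion = report@withoutExclusion,
             config = report@config,
             note = paste("Structure votes are not fully independent;",
                          "binomial P-values should be discounted to some",
                          "extent.")),
        jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(vp, sp, jp))
}
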