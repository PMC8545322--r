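## Generalized Initial Cluster Analysis: congruence between a DC-score
## ordering and structural contacts, as a -log10 P S-score.

## Candidate segment lengths are the array positions of the distinguished
## elements (a segment not ending at a distinguished element can never be
## optimal for the enrichment term). At the k-th distinguished position X:
##   enrichment: upper hypergeometric tail P(K >= k | X draws from L, D);
##   ordering:   one-sided Spearman concordance between the appearance
##               order of the first k distinguished elements and their
##               structural-distance ranks, normal approximation
##               z = rho * sqrt(k - 1) (p = 1 when k < 3).
## The combined statistic at X is Fisher's chi^2 (4 df) of the two, which
## is monotone in their product, and the score statistic is the minimum
## over candidate X. Its attained significance is computed exactly (full
## enumeration of placements x orderings) when the null space is small,
## and by the Bonferroni-corrected Fisher p otherwise (conservative).
ICA_EXACT_BUDGET <- 4e6

#' Congruence S-score of an ordered pair array
#'
#' Measures how surprisingly the structural contacts (distinguished
#' entries) concentrate at the top of the DC-score ordering, rewarding
#' additionally the early appearance of the spatially closest contacts.
#' Returns `S = -log10(P)`; `S = 0` when the array holds no distinguished
#' element.
#'
#' @param array a [PairArray] (or a data.frame with columns `dc`, `dist`,
#'   `distinguished` already sorted by `dc` descending).
#' @return An [IcaResult].
#' @export
icaScore <- function(array) {
    if (is(array, "PairArray")) {
        e <- pairEntries(array)
        L <- array@L; D <- array@D
    } else {
        e <- array
        L <- nrow(e); D <- sum(e$distinguished)
    }
    if (L < 1L) stop("empty pair array")
    if (D > L) stop("more distinguished elements than entries")
    if (D == 0L)
        return(new("IcaResult", sScore = 0, pValue = 1, bestCutoff = 0L,
                   dAtCutoff = 0L, L = as.integer(L), D = 0L,
                   components = c(enrichment_p = 1, ordering_p = 1),
                   method = "degenerate"))

    dPos <- which(e$distinguished)              # candidate X values
    ## distance ranks among distinguished (1 = closest), ties broken by
    ## the array's own (a, b) order, i.e. by position
    dd <- e$dist[dPos]
    distRank <- rank(dd, ties.method = "first")

    k <- seq_len(D)
    logPh <- stats::phyper(k - 1L, D, L - D, dPos,
                           lower.tail = FALSE, log.p = TRUE)
    logPo <- vapply(k, function(kk) orderingLogP(distRank[seq_len(kk)]),
                    numeric(1))
    logProd <- logPh + logPo
    bestIdx <- which.min(logProd)

    if (choose(L, D) * factorial(D) <= ICA_EXACT_BUDGET) {
        phTab <- matrix(stats::phyper(rep(k - 1L, each = L), D, L - D,
                                      rep(seq_len(L), D),
                                      lower.tail = FALSE),
                        nrow = L)
        p <- ica_exact_tail_cpp(L, D, exp(min(logProd)), phTab)
        method <- "exact"
        logP <- log(p)
    } else {
        logFisher <- stats::pchisq(-2 * logProd, df = 4,
                                   lower.tail = FALSE, log.p = TRUE)
        bestIdx <- which.min(logFisher)
        logP <- min(0, min(logFisher) + log(length(dPos)))
        method <- "bonferroni"
    }
    pValue <- max(exp(logP), 1e-300)
    new("IcaResult", sScore = -log10(pValue), pValue = pValue,
        bestCutoff = as.integer(dPos[bestIdx]), dAtCutoff = as.integer(bestIdx),
        L = as.integer(L), D = as.integer(D),
        components = c(enrichment_p = exp(logPh[bestIdx]),
                       ordering_p = exp(logPo[bestIdx])),
        method = method)
}

## log one-sided p that the concordance between appearance order 1..k and
## the relative order of the given distance ranks is as large as observed.
orderingLogP <- function(ranks) {
    k <- length(ranks)
    if (k < 3L) return(0)
    rel <- rank(ranks, ties.method = "first")
    rho <- 1 - 6 * sum((rel - seq_len(k))^2) / (k * (k^2 - 1))
    stats::pnorm(rho * sqrt(k - 1), lower.tail = FALSE, log.p = TRUE)
}

#' Difference of two comparable S-scores
#'
#' S-scores are comparable only when computed from arrays with identical L
#' and D, which holds by construction for the two pair arrays of one
#' structure; a mismatch is a hard error.
#'
#' @param s1,s2 [IcaResult]s for the same structure under the two MSAs.
#' @return `sScore(s1) - sScore(s2)`; positive favors the first MSA.
#' @export
deltaS <- function(s1, s2) {
    if (s1@L != s2@L || s1@D != s2@D)
        stop(sprintf(
            "S-scores are not comparable: L = %d/%d, D = %d/%d differ",
            s1@L, s2@L, s1@D, s2@D))
    s1@sScore - s2@sScore
}

#' Per-cutoff ICA diagnostics
#'
#' @param array a [PairArray].
#' @return data.frame with one row per candidate cutoff X: `X`, `d`,
#'   enrichment and ordering p-values and the Fisher-combined p.
#' @export
icaDiagnostics <- function(array) {
    e <- pairEntries(array)
    L <- array@L; D <- array@D
    if (D == 0L) return(data.frame())
    dPos <- which(e$distinguished)
    distRank <- rank(e$dist[dPos], ties.method = "first")
    k <- seq_len(D)
    logPh <- stats::phyper(k - 1L, D, L - D, dPos,
                           lower.tail = FALSE, log.p = TRUE)
    logPo <- vapply(k, function(kk) orderingLogP(distRank[seq_len(kk)]),
                    numeric(1))
    data.frame(X = dPos, d = k,
               enrichment_p = exp(logPh), ordering_p = exp(logPo),
               combined_p = stats::pchisq(-2 * (logPh + logPo), df = 4,
                                          lower.tail = FALSE))
}
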