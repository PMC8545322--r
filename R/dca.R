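## Direct coupling analysis: sequence reweighting, pseudo-likelihood Potts
## fitting, APC-corrected Frobenius norm scores, and score matrix IO.

#' Identity-based sequence reweighting
#'
#' Downweights redundant records: each record's weight is the reciprocal of
#' the number of records (itself included) whose identity over scored
#' columns meets `threshold`. Positions holding nulls count as mismatches
#' and the denominator is the number of scored columns, so the weights only
#' depend on the scored alignment text.
#'
#' @param msa an [Msa].
#' @param threshold identity threshold in (0, 1]; default 0.8, the midpoint
#'   of the commonly explored 70/80/90 percent grid.
#' @return A [SequenceWeights].
#' @export
computeWeights <- function(msa, threshold = 0.8) {
    if (threshold <= 0 || threshold > 1)
        stop("reweighting threshold must lie in (0, 1]")
    if (msaLength(msa) < 1L) stop("empty MSA")
    X <- msaStateMatrix(msa)
    w <- compute_weights_cpp(X, threshold)
    new("SequenceWeights", weights = as.numeric(w), meff = sum(w),
        threshold = threshold)
}

allPairs <- function(L) {
    i <- rep(seq_len(L - 1L), times = (L - 1L):1L)
    j <- sequence((L - 1L):1L) + i
    cbind(i = i, j = j)
}

#' Fit a Potts model by weighted pseudo-likelihood maximization
#'
#' Maximizes the sequence-weighted pseudo-log-likelihood of a dense
#' 21-state Potts model (20 amino acids plus a null/other state) over the
#' scored columns, minus L2 penalties: `0.01 * ||h||^2` on the fields and
#' `regStrength * (nCols - 1) * ||e||^2` on the couplings (the pairwise
#' penalty scaling standard in pseudo-likelihood DCA). Optimization is
#' quasi-Newton (L-BFGS-B) from a zero start, run to projected-gradient
#' tolerance `gradTol` or `maxIter` iterations; non-convergence is recorded
#' in the model metadata rather than raised.
#'
#' @param msa an [Msa] with at least two records and two scored columns.
#' @param weights optional [SequenceWeights]; computed at the default
#'   threshold when missing.
#' @param regStrength pairwise regularization strength (default 0.2;
#'   0.1 and 0.3 are the usual alternates).
#' @param maxIter iteration cap for the quasi-Newton optimizer.
#' @param gradTol gradient-norm stopping tolerance.
#' @return A [PottsModel].
#' @export
fitPotts <- function(msa, weights = NULL, regStrength = 0.2,
                     maxIter = 150L, gradTol = 1e-3) {
    X <- msaStateMatrix(msa)
    L <- ncol(X)
    if (L < 2L) stop("need at least two scored columns")
    if (nrow(X) < 1L) stop("empty MSA")
    if (is.null(weights)) weights <- computeWeights(msa)
    w <- seqWeights(weights)
    if (length(w) != nrow(X)) stop("weights do not match the MSA records")
    q <- 21L
    pairs <- allPairs(L)
    npar <- q * L + nrow(pairs) * q * q
    lambdaH <- 0.01
    lambdaE <- regStrength * (L - 1)

    fit <- plm_fit_cpp(numeric(npar), X, w, lambdaH, lambdaE,
                       maxit = maxIter, pgtol = gradTol, m = 6L)
    if (!fit$converged)
        warning("pseudo-likelihood fit did not converge within ", maxIter,
                " iterations (gradient norm ",
                format(fit$gradInfNorm, digits = 3),
                "); partial model returned")
    fields <- matrix(fit$par[seq_len(q * L)], nrow = q)
    couplings <- array(fit$par[-seq_len(q * L)], dim = c(q, q, nrow(pairs)))
    new("PottsModel", nCols = L, nStates = q, fields = fields,
        pairs = pairs, couplings = couplings,
        metadata = list(regStrength = regStrength,
                        reweightThreshold = weights@threshold,
                        meff = meff(weights),
                        converged = fit$converged,
                        iterations = fit$iterations,
                        evaluations = fit$evaluations,
                        objective = fit$value))
}

## Zero-sum (Ising) gauge over the 20 amino-acid states of one block.
zeroSumGauge <- function(block) {
    rm <- rowMeans(block); cm <- colMeans(block); mm <- mean(block)
    sweep(sweep(block, 1, rm), 2, cm) + mm
}

#' APC-corrected Frobenius norm coupling scores
#'
#' For each column pair the coupling block is put in zero-sum gauge over
#' the 20 amino-acid states (the null/other state is excluded) and reduced
#' to its Frobenius norm `F(i,j)`; the average product correction then
#' subtracts `Fbar(i,.) * Fbar(.,j) / Fbar(.,.)`, the means taken excluding
#' the diagonal, removing background and phylogenetic signal.
#'
#' @param model a [PottsModel].
#' @return A [CouplingScores] with the APC-corrected scores (diagonal `NA`).
#' @export
frobeniusApc <- function(model) {
    L <- model@nCols
    Fm <- matrix(0, L, L)
    aa <- seq_len(20L)
    for (p in seq_len(nrow(model@pairs))) {
        blk <- zeroSumGauge(model@couplings[aa, aa, p])
        f <- sqrt(sum(blk^2))
        i <- model@pairs[p, 1]; j <- model@pairs[p, 2]
        Fm[i, j] <- f; Fm[j, i] <- f
    }
    scores <- apcCorrect(Fm)
    new("CouplingScores", scores = scores, nCols = L,
        metadata = c(model@metadata, list(source = "internal")))
}

#' Average product correction of a symmetric score matrix
#'
#' @param Fm symmetric matrix of raw Frobenius norms.
#' @return Matrix of `F(i,j) - Fbar(i,.) * Fbar(.,j) / Fbar(.,.)` with the
#'   means taken over off-diagonal entries; diagonal set to `NA`.
#' @export
apcCorrect <- function(Fm) {
    L <- nrow(Fm)
    diag(Fm) <- NA
    rowM <- rowMeans(Fm, na.rm = TRUE)
    allM <- mean(Fm[upper.tri(Fm)])
    out <- Fm - outer(rowM, rowM) / allM
    diag(out) <- NA
    out
}

#' Import a precomputed coupling-score matrix
#'
#' Reads the flat whitespace-separated L x L numeric text emitted by
#' standard DCA tools. Asymmetries up to 1e-6 are silently symmetrized by
#' averaging; anything larger is an error.
#'
#' @param path matrix file.
#' @param nCols expected dimension (the MSA's scored-column count).
#' @return A [CouplingScores] with source `"imported"`.
#' @export
importScores <- function(path, nCols) {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != nCols || ncol(m) != nCols)
        stop(sprintf("score matrix is %d x %d but the MSA has %d scored columns",
                     nrow(m), ncol(m), nCols))
    asym <- max(abs(m - t(m)))
    if (asym > 1e-6)
        stop(sprintf("score matrix asymmetry %.3g exceeds tolerance 1e-6", asym))
    m <- (m + t(m)) / 2
    diag(m) <- NA
    new("CouplingScores", scores = m, nCols = as.integer(nCols),
        metadata = list(source = "imported", path = path))
}

#' Write a coupling-score matrix as flat numeric text
#'
#' @param scores a [CouplingScores].
#' @param path output file (whitespace-separated L x L text; the undefined
#'   diagonal is written as 0).
#' @return `path`, invisibly.
#' @export
exportScores <- function(scores, path) {
    m <- dcScores(scores)
    diag(m) <- 0
    utils::write.table(format(m, digits = 10, trim = TRUE), path,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    invisible(path)
}
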