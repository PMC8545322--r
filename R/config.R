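#' Run configuration
#'
#' Bundles the tunable parameters of a comparison with their defaults and
#' documented ranges. The configuration is serialized verbatim into every
#' report, so a run can be reproduced byte for byte.
#'
#' @param z sidechain contact cutoff in Angstrom (default 4; 5 and 6 are
#'   common alternates).
#' @param minSeparation minimum number of intervening residues between
#'   scored pairs (default 5), excluding backbone-imposed contacts.
#' @param reweightThreshold sequence reweighting identity threshold
#'   (default 0.8; 0.7 and 0.9 are the usual alternates).
#' @param regStrength pairwise regularization strength of the Potts fit
#'   (default 0.2; alternates 0.1 and 0.3).
#' @param sdMultiplier distance-discrepancy exclusion threshold in sample
#'   SD units (default 2).
#' @param diversityCutoff structure diversity identity ceiling
#'   (default 0.65).
#' @param nullColumnFraction flush-alignment column mask threshold
#'   (default 0.5: columns with more than 50 percent nulls are unscored).
#' @param redundancyCutoff record dereplication identity threshold
#'   (default 0.95).
#' @param maxIter,gradTol Potts optimizer caps.
#' @param seed integer seed stamped into reports.
#' @return A named list with class checks applied.
#' @export
ecompassConfig <- function(z = 4.0, minSeparation = 5L,
                           reweightThreshold = 0.8, regStrength = 0.2,
                           sdMultiplier = 2.0, diversityCutoff = 0.65,
                           nullColumnFraction = 0.5, redundancyCutoff = 0.95,
                           maxIter = 150L, gradTol = 1e-3, seed = 1L) {
    stopifnot(z > 0, minSeparation >= 0,
              reweightThreshold > 0, reweightThreshold <= 1,
              regStrength > 0, sdMultiplier > 0,
              diversityCutoff > 0, diversityCutoff <= 1,
              nullColumnFraction >= 0, nullColumnFraction <= 1,
              redundancyCutoff > 0, redundancyCutoff <= 1,
              maxIter >= 1, gradTol > 0)
    list(z = z, minSeparation = as.integer(minSeparation),
         reweightThreshold = reweightThreshold, regStrength = regStrength,
         sdMultiplier = sdMultiplier, diversityCutoff = diversityCutoff,
         nullColumnFraction = nullColumnFraction,
         redundancyCutoff = redundancyCutoff,
         maxIter = as.integer(maxIter), gradTol = gradTol,
         seed = as.integer(seed))
}

#' Rerun a comparison over the hyperparameter robustness grid
#'
#' Repeats [compareMsas()] over the 3 x 3 x 3 grid of contact cutoffs
#' (4/5/6 Angstrom), reweighting thresholds (0.7/0.8/0.9) and
#' regularization strengths (0.1/0.2/0.3) and reports, per setting, the
#' favored MSA and vote significance, plus whether the favored-MSA sign is
#' consistent across the grid.
#'
#' @param msa1,msa2,structures,... passed to [compareMsas()].
#' @param config base configuration; grid values override its `z`,
#'   `reweightThreshold` and `regStrength`.
#' @param useExclusion summarize with outlier exclusion?
#' @return List with `grid` (data.frame of settings and results) and
#'   `consistent` (logical).
#' @export
robustnessGrid <- function(msa1, msa2, structures,
                           config = ecompassConfig(), useExclusion = TRUE,
                           ...) {
    grid <- expand.grid(z = c(4, 5, 6),
                        reweightThreshold = c(0.7, 0.8, 0.9),
                        regStrength = c(0.1, 0.2, 0.3))
    rows <- lapply(seq_len(nrow(grid)), function(g) {
        cfg <- config
        cfg$z <- grid$z[g]
        cfg$reweightThreshold <- grid$reweightThreshold[g]
        cfg$regStrength <- grid$regStrength[g]
        rep <- compareMsas(msa1, msa2, structures, config = cfg, ...)
        b <- comparisonSummary(rep, if (useExclusion) "with" else "without")
        data.frame(grid[g, ], n1 = b$n1, n2 = b$n2,
                   deltaSMean = b$deltaSMean, negLog10P = b$negLog10P,
                   favored = sign(b$deltaSMean))
    })
    out <- do.call(rbind, rows)
    list(grid = out, consistent = length(unique(out$favored)) == 1L)
}
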