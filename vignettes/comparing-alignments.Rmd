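---
title: "Comparing two large protein alignments by direct-coupling congruence"
author: "ecompass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two large protein alignments by direct-coupling congruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecompass)
```

## The problem and the model

Benchmark-based evaluation of multiple sequence alignment (MSA) methods
breaks down for superfamily-scale alignments with tens or hundreds of
thousands of sequences: curated benchmarks are small, possibly wrong, and
say nothing about the sequences they omit. `ecompass` takes a different
route. In an accurate alignment of a protein family, residue positions
that are in 3D contact coevolve, and that covariation is recoverable from
the alignment columns by direct coupling analysis (DCA). Given two
competing alignments $M_1$ and $M_2$ of the *same* sequences and a modest
set of reference structures, the package asks, per structure: which
alignment's inferred couplings agree better with the observed contacts?

The pipeline is:

1. **Scored columns.** For match-state alignments (A2M, Stockholm with a
   reference line) the match columns are scored. Flush alignments drop
   columns with more than 50% null characters (`filterNullColumns()`).
2. **DCA.** A 21-state Potts model (20 amino acids plus one null/other
   state) is fit to each alignment's scored columns by weighted
   pseudo-likelihood maximization, and each column pair is reduced to the
   average product corrected (APC) Frobenius norm of its coupling block in
   zero-sum gauge, computed over the 20 amino-acid states. These DC scores
   are treated as purely ordinal.
3. **Comparable pair arrays.** For each reference structure, the residue
   set $R$ aligned to scored columns in *both* MSAs defines, for every
   residue pair with at least $m = 5$ intervening residues, one entry in
   each of two equal-sized arrays ($K_1'$, $K_2'$), each sorted by its own
   MSA's DC scores. Pairs whose minimum sidechain-atom distance is at most
   $z = 4$ Å are the *distinguished* (contact) entries.
4. **Congruence score.** A generalized initial-cluster statistic turns
   each array into $S = -\log_{10} P$, where small $P$ means contacts
   crowd the top of the DC ranking, with the spatially closest contacts
   earliest. Because both arrays share $L$ and $D$ exactly,
   $\Delta S = S_1 - S_2$ is a per-structure vote.
5. **Outlier exclusion.** Structures misaligned *within* an MSA are
   detected from geometry alone: $\Delta\mathfrak{D}_{ij}$, the mean
   absolute difference of aligned C$\alpha$ distances between structures
   $i$ and $j$, is averaged into $\Delta\mathfrak{D}_i$ and structures at
   or above 2 sample SDs over the mean are removed iteratively. The
   S-scores never enter this decision.
6. **Verdict.** $\overline{\Delta S}$ and a two-tailed equiprobable
   binomial P-value over the $(N_1, N_2)$ vote, both with and without the
   excluded structures.

## The congruence statistic and its p-value

The array has $L$ entries, $D$ distinguished. Candidate cutoffs $X$ are
the positions of distinguished elements (no other initial segment can be
optimal). At the $k$-th distinguished position the *enrichment* term is
the hypergeometric upper tail $P(K \ge k \mid X, L, D)$; the *ordering*
term is the one-sided normal approximation to the Spearman concordance
between the appearance order of those $k$ contacts and their
structural-distance ranks ($p = 1$ for $k < 3$). Fisher's
$\chi^2_4$ combination of the two is monotone in their product, so the
optimized statistic is $T = \min_k p_{\mathrm{hyper}}(k)\,
p_{\mathrm{order}}(k)$.

Turning $T$ into a calibrated $P$ is where a design choice was genuinely
open. A Bonferroni correction of the Fisher p over the candidate cutoffs
is simple, but at small $(L, D)$ it is badly off: the null is discrete
(placements times orderings), the candidate tests are nested and strongly
dependent, and the true tail of $T$ can differ from the Bonferroni bound
by more than an order of magnitude. The package therefore computes the
**exact** tail probability of $T$ — enumerating all $\binom{L}{D} D!$
placement/ordering configurations — whenever that product is at most
$4 \times 10^6$, and falls back to the Bonferroni-corrected Fisher
combination for large arrays, where the correction's conservatism is mild
on the $-\log_{10}$ scale and provably never anti-conservative. The
`method` field of an `IcaResult` records which route produced the value.
Both routes are monotone in $T$, so $\Delta S$ comparisons within one
structure are unaffected by the crossover. All arithmetic runs in log
space so S-scores up to about 300 remain representable.

Null calibration of the large-array route is property-tested: across
$10^4$ simulated null arrays at $L = 200$, $D = 20$, the fraction with
$P \le \alpha$ stays below $1.5\alpha$ (conservatism is acceptable,
anti-conservatism is not).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `z` | 4 Å | sidechain contact cutoff defining distinguished pairs (5/6 Å are common alternates); glycine falls back to C$\alpha$ |
| `minSeparation` | 5 | intervening residues required between scored pairs, excluding backbone-driven contacts |
| `reweightThreshold` | 0.8 | identity threshold for sequence reweighting; 0.8 is the midpoint of the commonly explored 0.7/0.8/0.9 grid |
| `regStrength` | 0.2 | pairwise L2 penalty scale; the penalty is `regStrength * (nCols - 1) * ||e||^2` plus a fixed `0.01 * ||h||^2` on fields, the scaling standard in pseudo-likelihood DCA |
| `sdMultiplier` | 2 | discrepancy exclusion threshold in sample SDs |
| `diversityCutoff` | 0.65 | structures sharing more identity than this are thinned before voting |
| `nullColumnFraction` | 0.5 | flush columns with strictly more nulls than this are unscored |
| `redundancyCutoff` | 0.95 | record dereplication threshold for `purgeRedundancy()` |

On the regularization: published descriptions of comparable pipelines name
an "L1" pairwise strength for the same 0.1/0.2/0.3 knob; this
implementation uses the L2 (quadratic) penalty that pseudo-likelihood DCA
practice and its convexity argument favor, and treats the strength values
as naming the same knob. The reweighting default of 0.8 is the midpoint of
the grid commonly explored; no single canonical default exists.

Numerical choices: fitting starts from zero parameters (no random
restarts), runs L-BFGS to a projected-gradient infinity-norm below `1e-3`
or 150 iterations, and records non-convergence in the model metadata
instead of failing. DC-score ties in pair arrays break lexicographically
by residue pair; distance ties among distinguished elements break by array
order. A zero SD in the exclusion loop short-circuits to "no removals"
(removing everything on a degenerate tie would be absurd). The
$\Delta\mathfrak{D}$ matrix is computed once and frozen; only the
mean/SD pair is re-estimated between exclusion passes, and a structure is
tested against summary statistics that include its own value — both
choices are what make the published z-score arithmetic reproduce exactly.
With fewer than three usable structures the exclusion step is skipped
with a warning rather than estimated from an undefined SD.

## The simulation harness

`makePlantedModel()` builds what the real data cannot give us: a family
whose true contacts are known. A bead chain (3.8 Å steps, self-avoiding,
confined to protein-like density) supplies geometry; the `nContacts`
closest bead pairs with sequence separation at least 6 and distance at
most 8 Å become the contact graph; couplings exist *only* there (20x20
blocks, Normal(0, `couplingScale`), zero-sum gauge), fields are
Normal(0, 0.5). Gold standards are sampled from this model by single-chain
Gibbs sampling over the 20 amino-acid states (burn-in 500 sweeps,
thinning 10), so they are gap-free by construction; `corruptAlignment()`
introduces the only nulls. `spScore()` measures the fraction of gold
co-aligned residue pairs preserved — the standard sum-of-pairs accuracy.

Corruption deliberately mimics how automated aligners actually fail on
large families: subgroups of sequences slip out of register *together*
(the same failure mode the distance-discrepancy filter exists to catch on
real data). Six seeded shift profiles — a suffix start column plus a shift
of up to `maxShift` — are assigned across records with a small per-record
jitter, and a seeded permutation makes the corrupted subset nested in the
fraction, so damage grows gradually and reproducibly. In the
`sRatioExperiment()` loop the record anchoring the pseudo-structure's
residue-to-column map is held fixed: on real data a reference whose own
row is misaligned is removed by the distance-discrepancy exclusion before
$\overline{\Delta S}$ is trusted, and with a single simulated reference
that safeguard cannot operate — a corrupted anchor turns the score into
an all-or-nothing coin flip instead of a measure of family-level
alignment quality. Designs in which
each record is damaged independently turn out to be poor stand-ins: a
wholesale per-record shift makes the single reference row's map an
all-or-nothing event, while shifts into private gap columns are removed
by the null-column mask before scoring and so never reach the coupling
fit. Register-level corruption is what actually fragments the
covariation signal the way real misalignment does.

Defaults were calibrated once for a desk-scale validation loop: 60
columns, 40 contacts, coupling scale 0.7 and 500 sampled sequences give an
alignment in which pseudo-likelihood DCA recovers planted contacts with
high precision while the congruence score retains dynamic range — at
markedly stronger couplings the contact ranking is so robust that the
score saturates and stops responding to anything short of catastrophic
corruption, which would make the validation loop uninformative; the
full-scale regime (5000 sequences) is a parameter away. The default
corruption grid (fractions 0, 0.4, 0.7, 1) spans that response range. The `sRatioExperiment()`
driver reproduces the validation logic: for each model, score the gold
standard ($S^\circ$) and a corrupted realignment ($S$) against the bead
pseudo-structure (contact cutoff 8 Å, the planting cutoff, since beads
have no sidechains) and relate $S/S^\circ$ to the SP accuracy.

What the simulations do *not* emulate: phylogenetic correlation between
sequences (Gibbs draws are only weakly autocorrelated, real families are
tree-structured), gapped homology, paralogy, or structures that disagree
with the family (the bead chain is the generative truth). Passing the
simulation suite therefore demonstrates that the statistic tracks
alignment accuracy when the coupling model is the data-generating process;
on real data the DCA model is misspecified and the method's claims are
correspondingly relative, not absolute.

One honest wrinkle: with gap-free gold standards, a contiguous block shift
leaves the prefix before the earliest shifted block co-aligned, so at
corruption fraction 1 the SP score plateaus well above zero rather than
vanishing; tests assert the monotone decline and the gap to the
uncorrupted score, not an exact floor.

## Limitations

- The method is strictly relative: it ranks two MSAs of the same
  sequences and assigns no absolute accuracy to either.
- Structure votes are not independent (homologous structures share
  evolutionary history); reported binomial P-values should be discounted
  to some extent, as the report footnote states.
- One conformation per protein: alternative conformations of the same
  family are not reconciled, a known avenue for future work.
- Exact congruence p-values are available only for small arrays; large
  arrays use a conservative bound, so very small printed $S$ differences
  between enormous arrays should not be over-read.
- The dense Potts fit is quadratic in columns and memory-hungry beyond a
  few hundred scored columns; precomputed coupling matrices from external
  DCA tools can be imported instead (`importScores()`).

## A worked desk-scale example

```{r example, eval = FALSE}
library(ecompass)

pm    <- makePlantedModel(nCols = 30, nContacts = 20, seed = 301)
gold  <- sampleMsa(pm, n = 200, seed = 302)
bad   <- filterNullColumns(corruptAlignment(gold, 0.5, seed = 303))
s1    <- frobeniusApc(fitPotts(gold@msa, computeWeights(gold@msa)))
s2    <- frobeniusApc(fitPotts(bad, computeWeights(bad)))
structs <- lapply(1:3, goldReferenceStructure, gold = gold)

report <- compareMsas(gold@msa, bad, structs,
                      config = ecompassConfig(z = 8),
                      scores1 = s1, scores2 = s2,
                      structureRows = cbind(1:3, 1:3))
report
verdicts(report)
```

The gold standard should win every vote, and does in the packaged tests;
the same machinery applied to two real alignments (FASTA/A2M/Stockholm in,
PDB references) is the command-line `compare` workflow in
`inst/scripts/ecompass.R`.
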