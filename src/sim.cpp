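#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Single-chain Gibbs sampler for a Potts model restricted to the first
// nSample states (gold standards are sampled over the 20 amino-acid states;
// the null/other state is never emitted). fields is q x L; pairs (P x 2,
// 1-based, i < j) and couplings (q x q x P) define the interaction graph.
// Returns n sequences (rows) recorded every `thin` sweeps after `burnin`.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericMatrix fields, IntegerMatrix pairs,
                               NumericVector couplings, int nSample,
                               int n, int burnin, int thin, int seed) {
    const int q = fields.nrow(), L = fields.ncol(), P = pairs.nrow();
    if (n <= 0) stop("number of sampled sequences must be positive");
    std::mt19937 gen((unsigned)seed);
    auto runif01 = [&]() { return (gen() + 0.5) / 4294967296.0; };

    // neighbour lists: for site i, (other site, block offset, orientation)
    struct Nb { int j; int base; bool first; };
    std::vector<std::vector<Nb>> nbrs(L);
    for (int p = 0; p < P; ++p) {
        const int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
        nbrs[i].push_back({j, p * q * q, true});
        nbrs[j].push_back({i, p * q * q, false});
    }
    const double *J = couplings.begin();

    std::vector<int> x(L);
    for (int i = 0; i < L; ++i)
        x[i] = (int)(runif01() * nSample); // 0-based state
    std::vector<double> logits(nSample), pr(nSample);

    IntegerMatrix out(n, L);
    int recorded = 0;
    const long totalSweeps = (long)burnin + (long)thin * n;
    for (long sweep = 1; sweep <= totalSweeps; ++sweep) {
        for (int i = 0; i < L; ++i) {
            for (int a = 0; a < nSample; ++a) logits[a] = fields(a, i);
            for (const Nb &nb : nbrs[i]) {
                const int xo = x[nb.j];
                if (nb.first) { // i is the first index: J(a, x_j)
                    const double *col = J + nb.base + xo * q;
                    for (int a = 0; a < nSample; ++a) logits[a] += col[a];
                } else {        // i is the second index: J(x_j, a)
                    const double *row = J + nb.base + xo;
                    for (int a = 0; a < nSample; ++a) logits[a] += row[a * q];
                }
            }
            double mx = logits[0];
            for (int a = 1; a < nSample; ++a) if (logits[a] > mx) mx = logits[a];
            double Z = 0.0;
            for (int a = 0; a < nSample; ++a) {
                pr[a] = std::exp(logits[a] - mx);
                Z += pr[a];
            }
            double u = runif01() * Z, acc = 0.0;
            int pick = nSample - 1;
            for (int a = 0; a < nSample; ++a) {
                acc += pr[a];
                if (u <= acc) { pick = a; break; }
            }
            x[i] = pick;
        }
        if (sweep > burnin && (sweep - burnin) % thin == 0 && recorded < n) {
            for (int i = 0; i < L; ++i) out(recorded, i) = x[i] + 1;
            ++recorded;
        }
    }
    return out;
}

// Sum-of-pairs agreement between two alignments of the same sequences.
// goldCol/testCol map (sequence, residue index) -> alignment column
// (0 = residue absent); goldRes/testRes map (sequence, column) -> residue
// index (0 = null character). Returns c(#co-aligned pairs preserved, #gold
// co-aligned pairs).
// [[Rcpp::export]]
NumericVector sp_counts_cpp(IntegerMatrix goldCol, IntegerMatrix goldRes,
                            IntegerMatrix testCol, IntegerMatrix testRes) {
    const int N = goldCol.nrow(), R = goldCol.ncol();
    double num = 0.0, den = 0.0;
    for (int s = 0; s < N; ++s) {
        for (int t = s + 1; t < N; ++t) {
            for (int r = 0; r < R; ++r) {
                const int cg = goldCol(s, r);
                if (cg == 0) break; // residues exhausted for sequence s
                const int partner = goldRes(t, cg - 1);
                if (partner == 0) continue; // not co-aligned in gold
                den += 1.0;
                const int ct = testCol(s, r);
                if (ct == 0) continue;
                if (testRes(t, ct - 1) == partner) num += 1.0;
            }
        }
    }
    return NumericVector::create(num, den);
}
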