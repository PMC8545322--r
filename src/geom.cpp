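#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Minimum pairwise Euclidean distance between two residues' atom sets.
// atoms: all atom coordinates stacked (nAtoms x 3); starts: 1-based first
// atom index per residue; counts: atoms per residue. Returns the n x n
// matrix of minimum inter-atom distances (NA where a residue has no atoms).
// [[Rcpp::export]]
NumericMatrix min_pairwise_dist_cpp(NumericMatrix atoms, IntegerVector starts,
                                    IntegerVector counts) {
    const int n = starts.size();
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        out(i, i) = 0.0;
        for (int j = i + 1; j < n; ++j) {
            double best = std::numeric_limits<double>::infinity();
            for (int a = starts[i] - 1; a < starts[i] - 1 + counts[i]; ++a) {
                for (int b = starts[j] - 1; b < starts[j] - 1 + counts[j]; ++b) {
                    const double dx = atoms(a, 0) - atoms(b, 0);
                    const double dy = atoms(a, 1) - atoms(b, 1);
                    const double dz = atoms(a, 2) - atoms(b, 2);
                    const double d2 = dx * dx + dy * dy + dz * dz;
                    if (d2 < best) best = d2;
                }
            }
            double d = (counts[i] > 0 && counts[j] > 0)
                           ? std::sqrt(best) : NA_REAL;
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}
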