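#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One-sided upper normal tail, matching R's pnorm(lower.tail = FALSE).
static inline double pnorm_upper(double z) {
    return 0.5 * std::erfc(z / std::sqrt(2.0));
}

// Ordering p-value for the first k entries of a distinguished-rank
// permutation: Spearman concordance between the appearance order 1..k and
// the relative order of the distance ranks, one-sided via the normal
// approximation z = rho * sqrt(k - 1); p = 1 when k < 3.
static double ordering_p(const std::vector<int> &perm, int k) {
    if (k < 3) return 1.0;
    double ss = 0.0;
    for (int u = 0; u < k; ++u) {
        int r = 1;
        for (int v = 0; v < k; ++v)
            if (perm[v] < perm[u]) ++r;
        const double d = r - (u + 1);
        ss += d * d;
    }
    const double rho = 1.0 - 6.0 * ss / ((double)k * (k * (double)k - 1.0));
    return pnorm_upper(rho * std::sqrt((double)k - 1.0));
}

// Exact tail probability P(T <= tObs) of the congruence statistic
// T = min_k phTab(p_k, k) * po(perm, k), under the null that the D
// distinguished positions p_1 < ... < p_D are a uniform subset of 1..L and
// the distance-rank order among them is an independent uniform permutation.
// phTab is the L x D table of upper hypergeometric tails P(K >= d | X = x).
// Enumerates all C(L, D) placements and all D! orderings.
// [[Rcpp::export]]
double ica_exact_tail_cpp(int L, int D, double tObs, NumericMatrix phTab) {
    const double tol = tObs * (1.0 + 1e-9) + 1e-300;
    // precompute ordering p for every permutation prefix
    std::vector<int> base(D);
    for (int i = 0; i < D; ++i) base[i] = i + 1;
    std::vector<std::vector<double>> poAll;
    {
        std::vector<int> perm = base;
        do {
            std::vector<double> po(D);
            for (int k = 1; k <= D; ++k) po[k - 1] = ordering_p(perm, k);
            poAll.push_back(po);
        } while (std::next_permutation(perm.begin(), perm.end()));
    }
    const double nperm = (double)poAll.size();

    // enumerate placements with an odometer
    std::vector<int> pos(D);
    for (int i = 0; i < D; ++i) pos[i] = i + 1;
    double hits = 0.0, total = 0.0;
    std::vector<double> ph(D);
    for (;;) {
        for (int k = 0; k < D; ++k) ph[k] = phTab(pos[k] - 1, k);
        for (size_t pi = 0; pi < poAll.size(); ++pi) {
            const std::vector<double> &po = poAll[pi];
            double mn = ph[0] * po[0];
            for (int k = 1; k < D; ++k) {
                const double v = ph[k] * po[k];
                if (v < mn) mn = v;
            }
            if (mn <= tol) hits += 1.0;
        }
        total += nperm;
        // advance odometer
        int k = D - 1;
        while (k >= 0 && pos[k] == L - (D - 1 - k)) --k;
        if (k < 0) break;
        ++pos[k];
        for (int u = k + 1; u < D; ++u) pos[u] = pos[u - 1] + 1;
    }
    return hits / total;
}
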