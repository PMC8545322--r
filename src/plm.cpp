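#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Sequence weights: weight(s) = 1 / #{t : identity(s,t) >= threshold}.
// Identity is measured over the scored columns passed in X (states 1..21);
// any position where either sequence holds the null/other state (21) counts
// as a mismatch, and the denominator is the number of scored columns.
// [[Rcpp::export]]
NumericVector compute_weights_cpp(IntegerMatrix X, double threshold) {
    const int N = X.nrow(), L = X.ncol();
    // row-major copy for cache-friendly pairwise scans
    std::vector<int> xr((size_t)N * L);
    for (int s = 0; s < N; ++s)
        for (int i = 0; i < L; ++i) xr[(size_t)s * L + i] = X(s, i);
    std::vector<int> nbr(N, 1); // each sequence neighbours itself
    for (int s = 0; s < N; ++s) {
        const int *a = &xr[(size_t)s * L];
        for (int t = s + 1; t < N; ++t) {
            const int *b = &xr[(size_t)t * L];
            int match = 0;
            for (int i = 0; i < L; ++i)
                if (a[i] == b[i] && a[i] != 21) ++match;
            if ((double)match / L >= threshold) { ++nbr[s]; ++nbr[t]; }
        }
    }
    NumericVector w(N);
    for (int s = 0; s < N; ++s) w[s] = 1.0 / nbr[s];
    return w;
}

// Core evaluation: weighted negative pseudo-log-likelihood plus L2
// penalties; gradient written into `grad`. Parameter layout as documented
// on the exported wrapper below.
static double plm_eval(const double *par, size_t nparTot, double *gradOut,
                       const IntegerMatrix &X, const NumericVector &w,
                       double lambda_h, double lambda_e) {
    const int q = 21, qq = q * q;
    const int N = X.nrow(), L = X.ncol();
    const size_t npair = (size_t)L * (L - 1) / 2;
    const size_t nf = (size_t)q * L;
    if (nparTot != nf + npair * qq)
        stop("parameter vector has wrong length");

    const double *h = par;
    const double *J = par + nf;

    // pair index of (i, j), i < j
    std::vector<size_t> pidx((size_t)L * L);
    {
        size_t p = 0;
        for (int i = 0; i < L - 1; ++i)
            for (int j = i + 1; j < L; ++j, ++p) {
                pidx[(size_t)i * L + j] = p;
                pidx[(size_t)j * L + i] = p;
            }
    }

    // expand couplings: Jf[(i*L+j)*qq + b*q + a] = coupling(a at i, b at j)
    std::vector<double> Jf((size_t)L * L * qq, 0.0);
    for (int i = 0; i < L - 1; ++i) {
        for (int j = i + 1; j < L; ++j) {
            const double *blk = J + pidx[(size_t)i * L + j] * qq;
            double *fij = &Jf[((size_t)i * L + j) * qq];
            double *fji = &Jf[((size_t)j * L + i) * qq];
            for (int b = 0; b < q; ++b)
                for (int a = 0; a < q; ++a) {
                    const double v = blk[(size_t)b * q + a];
                    fij[(size_t)b * q + a] = v;
                    fji[(size_t)a * q + b] = v;
                }
        }
    }

    std::vector<double> Gf((size_t)L * L * qq, 0.0); // per-orientation grad
    std::fill(gradOut, gradOut + nparTot, 0.0);
    double *gh = gradOut;

    // row-major copy of the states (0-based) for sequence-inner sweeps
    std::vector<int> xr((size_t)N * L);
    for (int s = 0; s < N; ++s)
        for (int i = 0; i < L; ++i) xr[(size_t)s * L + i] = X(s, i) - 1;

    // logits(a, i, s): h plus coupling contributions, built block by block
    // so each q x q block stays cache-resident across the sequence sweep
    std::vector<double> logits((size_t)N * L * q);
    for (int s = 0; s < N; ++s)
        std::memcpy(&logits[(size_t)s * nf], h, sizeof(double) * nf);
    for (int i = 0; i < L; ++i) {
        for (int j = 0; j < L; ++j) {
            if (j == i) continue;
            const double *blk = &Jf[((size_t)i * L + j) * qq];
            for (int s = 0; s < N; ++s) {
                const double *col = blk + (size_t)xr[(size_t)s * L + j] * q;
                double *li = &logits[(size_t)s * nf + (size_t)i * q];
                for (int a = 0; a < q; ++a) li[a] += col[a];
            }
        }
    }

    // site conditionals: probabilities overwrite the logits in place
    double nll = 0.0;
    for (int s = 0; s < N; ++s) {
        const double ws = w[s];
        for (int i = 0; i < L; ++i) {
            double *li = &logits[(size_t)s * nf + (size_t)i * q];
            const int xi = xr[(size_t)s * L + i];
            double mx = li[0];
            for (int a = 1; a < q; ++a) if (li[a] > mx) mx = li[a];
            double Z = 0.0;
            for (int a = 0; a < q; ++a) { li[a] = std::exp(li[a] - mx); Z += li[a]; }
            nll -= ws * (std::log(li[xi]) - std::log(Z));
            const double invZ = 1.0 / Z;
            double *gc = gh + (size_t)i * q;
            for (int a = 0; a < q; ++a) {
                li[a] *= invZ;
                gc[a] += ws * li[a];
            }
            gc[xi] -= ws;
        }
    }

    // coupling gradient: the site-i conditional writes orientation (i, j);
    // again block-major so the target block stays in cache
    for (int i = 0; i < L; ++i) {
        for (int j = 0; j < L; ++j) {
            if (j == i) continue;
            double *blk = &Gf[((size_t)i * L + j) * qq];
            for (int s = 0; s < N; ++s) {
                const double ws = w[s];
                const double *pi = &logits[(size_t)s * nf + (size_t)i * q];
                double *col = blk + (size_t)xr[(size_t)s * L + j] * q;
                for (int a = 0; a < q; ++a) col[a] += ws * pi[a];
                col[xr[(size_t)s * L + i]] -= ws;
            }
        }
    }

    // fold the two orientations back into the single-copy layout
    double *gJ = gradOut + nf;
    for (int i = 0; i < L - 1; ++i) {
        for (int j = i + 1; j < L; ++j) {
            double *out = gJ + pidx[(size_t)i * L + j] * qq;
            const double *gij = &Gf[((size_t)i * L + j) * qq];
            const double *gji = &Gf[((size_t)j * L + i) * qq];
            for (int b = 0; b < q; ++b)
                for (int a = 0; a < q; ++a)
                    out[(size_t)b * q + a] =
                        gij[(size_t)b * q + a] + gji[(size_t)a * q + b];
        }
    }

    // L2 penalties
    double pen = 0.0;
    for (size_t k = 0; k < nf; ++k) {
        pen += lambda_h * par[k] * par[k];
        gradOut[k] += 2.0 * lambda_h * par[k];
    }
    for (size_t k = nf; k < nparTot; ++k) {
        pen += lambda_e * par[k] * par[k];
        gradOut[k] += 2.0 * lambda_e * par[k];
    }
    return nll + pen;
}

// Weighted negative pseudo-log-likelihood of a dense 21-state Potts model
// plus L2 penalties, with its gradient. Parameter layout: fields h (q x L,
// column-major) followed by coupling blocks J_p (q x q, column-major) for
// ordered column pairs p = (i, j), i < j, enumerated i ascending then j.
// J_p(a, b) couples state a at column i with state b at column j.
// [[Rcpp::export]]
List plm_obj_grad_cpp(NumericVector par, IntegerMatrix X, NumericVector w,
                      double lambda_h, double lambda_e) {
    NumericVector grad(par.size());
    double v = plm_eval(par.begin(), par.size(), grad.begin(), X, w,
                        lambda_h, lambda_e);
    return List::create(_["value"] = v, _["grad"] = grad);
}

// ---------------------------------------------------------------------------
// In-process L-BFGS driver for the pseudo-likelihood fit. Keeping the
// optimization loop in C++ avoids copying the ~1e6-element parameter and
// gradient vectors through R on every iteration.

// [[Rcpp::export]]
List plm_fit_cpp(NumericVector par0, IntegerMatrix X, NumericVector w,
                 double lambda_h, double lambda_e, int maxit, double pgtol,
                 int m) {
    const size_t n = par0.size();
    std::vector<double> x(par0.begin(), par0.end()), g(n), xNew(n), gNew(n);
    double f = plm_eval(x.data(), n, g.data(), X, w, lambda_h, lambda_e);
    int nEval = 1;

    std::vector<std::vector<double>> S, Y;
    std::vector<double> rho, alpha(m), d(n);
    bool converged = false;
    int iter = 0;

    auto infNorm = [&](const std::vector<double> &v) {
        double mx = 0.0;
        for (double vi : v) { double a = std::fabs(vi); if (a > mx) mx = a; }
        return mx;
    };

    for (iter = 0; iter < maxit; ++iter) {
        if (infNorm(g) <= pgtol) { converged = true; break; }
        // two-loop recursion: d = -H g
        for (size_t k = 0; k < n; ++k) d[k] = -g[k];
        const int h = (int)S.size();
        for (int idx = h - 1; idx >= 0; --idx) {
            double a = 0.0;
            for (size_t k = 0; k < n; ++k) a += S[idx][k] * d[k];
            a *= rho[idx];
            alpha[idx] = a;
            for (size_t k = 0; k < n; ++k) d[k] -= a * Y[idx][k];
        }
        if (h > 0) {
            double yy = 0.0, sy = 0.0;
            for (size_t k = 0; k < n; ++k) {
                yy += Y[h - 1][k] * Y[h - 1][k];
                sy += S[h - 1][k] * Y[h - 1][k];
            }
            const double gamma = sy / yy;
            for (size_t k = 0; k < n; ++k) d[k] *= gamma;
        } else {
            const double gn = infNorm(g);
            const double scale = 1.0 / std::max(1.0, gn);
            for (size_t k = 0; k < n; ++k) d[k] *= scale;
        }
        for (int idx = 0; idx < h; ++idx) {
            double b = 0.0;
            for (size_t k = 0; k < n; ++k) b += Y[idx][k] * d[k];
            b *= rho[idx];
            for (size_t k = 0; k < n; ++k) d[k] += S[idx][k] * (alpha[idx] - b);
        }
        double gd = 0.0;
        for (size_t k = 0; k < n; ++k) gd += g[k] * d[k];
        if (gd >= 0) { // not a descent direction; restart from steepest descent
            S.clear(); Y.clear(); rho.clear();
            for (size_t k = 0; k < n; ++k) d[k] = -g[k];
            gd = 0.0;
            for (size_t k = 0; k < n; ++k) gd -= g[k] * g[k];
        }
        // backtracking Armijo line search
        const double c1 = 1e-4;
        double step = 1.0, fNew = f;
        bool ok = false;
        for (int ls = 0; ls < 30; ++ls) {
            for (size_t k = 0; k < n; ++k) xNew[k] = x[k] + step * d[k];
            fNew = plm_eval(xNew.data(), n, gNew.data(), X, w, lambda_h, lambda_e);
            ++nEval;
            if (fNew <= f + c1 * step * gd) { ok = true; break; }
            step *= 0.5;
        }
        if (!ok) break; // line search failure: give up at current iterate
        // curvature memory update
        std::vector<double> sv(n), yv(n);
        double sy = 0.0;
        for (size_t k = 0; k < n; ++k) {
            sv[k] = xNew[k] - x[k];
            yv[k] = gNew[k] - g[k];
            sy += sv[k] * yv[k];
        }
        x.swap(xNew); g.swap(gNew); f = fNew;
        if (sy > 1e-10) {
            if ((int)S.size() == m) {
                S.erase(S.begin()); Y.erase(Y.begin()); rho.erase(rho.begin());
            }
            S.push_back(std::move(sv));
            Y.push_back(std::move(yv));
            rho.push_back(1.0 / sy);
        }
    }
    if (infNorm(g) <= pgtol) converged = true;

    NumericVector parOut(x.begin(), x.end());
    return List::create(_["par"] = parOut, _["value"] = f,
                        _["iterations"] = iter, _["evaluations"] = nEval,
                        _["converged"] = converged,
                        _["gradInfNorm"] = infNorm(g));
}
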