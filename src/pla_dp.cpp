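#include <Rcpp.h>
using namespace Rcpp;

// Integer sequence encoding used throughout: 0 = gap, 1..4 = A,C,G,T, 5 = N.
// N scores as a mismatch against every letter including N.

static void sigTable(double alpha, double beta, double delta, double tab[6][6]) {
    for (int a = 0; a < 6; ++a)
        for (int b = 0; b < 6; ++b) {
            if (a == 0 && b == 0) tab[a][b] = 0.0;
            else if (a == 0 || b == 0) tab[a][b] = delta;
            else if (a == b && a != 5) tab[a][b] = alpha;
            else tab[a][b] = beta;
        }
}

// Fill the (m+1) x (n+1) x (p+1) score tensor S of the partially local
// three-way alignment of F, L, R.  Edges: S[i,0,0] = i*g, S[0,j,0] = j*g,
// S[0,0,k] = 2*g*k (free placement of R's prefix is handled in the interior,
// where S[i,j,k] may fall back on S[i,j,0] at no cost).  The k = 0 face is a
// plain pairwise Needleman-Wunsch of F and L; the j = 0 and i = 0 faces use
// the three-way score so that the absent sequence is penalized.
// [[Rcpp::export]]
NumericVector pla_fill_s(IntegerVector f, IntegerVector l, IntegerVector r,
                         double alpha, double beta, double delta,
                         double g, double W) {
    const int m = f.size(), n = l.size(), p = r.size();
    const R_xlen_t d1 = m + 1, d2 = n + 1;
    NumericVector Sv((double)d1 * d2 * (p + 1));
    double *S = REAL(Sv);
    const R_xlen_t sj = d1, sk = d1 * d2;
    double sig[6][6];
    sigTable(alpha, beta, delta, sig);
    // gamma for columns with at least one gap never sees the divisor W
    auto gam3 = [&](int a, int b, int c) {
        double s = sig[a][b] + sig[a][c] + sig[b][c];
        return (a && b && c) ? s / W : s;
    };

    // k = 0 face: pairwise F-L, edges at cost g, interior gaps at delta
    S[0] = 0.0;
    for (int i = 1; i <= m; ++i) S[i] = i * g;
    for (int j = 1; j <= n; ++j) S[j * sj] = j * g;
    for (int j = 1; j <= n; ++j) {
        const int lj = l[j - 1];
        double *cur = S + j * sj, *up = S + (j - 1) * sj;
        for (int i = 1; i <= m; ++i) {
            double best = up[i - 1] + sig[f[i - 1]][lj];
            double c = up[i] + delta;
            if (c > best) best = c;
            c = cur[i - 1] + delta;
            if (c > best) best = c;
            cur[i] = best;
        }
    }

    for (int k = 1; k <= p; ++k) {
        const int rk = r[k - 1];
        double *lev = S + k * sk, *lo = S + (k - 1) * sk;
        const double g_r = 2.0 * delta + 0.0;   // gamma('-','-',x) = 2 delta
        lev[0] = 2.0 * g * k;                   // R before both F and L
        // i = 0 face: L-R alignment without F, gamma-scored
        for (int j = 1; j <= n; ++j) {
            const int lj = l[j - 1];
            const double g_lr = sig[lj][rk] + 2.0 * delta;
            const double g_l = 2.0 * delta;
            double best = lo[(j - 1) * sj] + g_lr;
            double c = lev[(j - 1) * sj] + g_l;
            if (c > best) best = c;
            c = lo[j * sj] + g_r;
            if (c > best) best = c;
            lev[j * sj] = best;
        }
        // j = 0 face: F-R alignment before L starts; L gaps are penalized
        for (int i = 1; i <= m; ++i) {
            const int fi = f[i - 1];
            double best = lo[i - 1] + sig[fi][rk] + 2.0 * delta;
            double c = lev[i - 1] + 2.0 * delta;
            if (c > best) best = c;
            c = lo[i] + g_r;
            if (c > best) best = c;
            lev[i] = best;
        }
        // interior: seven gamma extensions plus the free R-prefix fallback
        for (int j = 1; j <= n; ++j) {
            const int lj = l[j - 1];
            const double g_lr = sig[lj][rk] + 2.0 * delta;
            const double g_l = 2.0 * delta;
            double *cur = lev + j * sj, *up = lev + (j - 1) * sj;
            double *dlo = lo + j * sj, *dup = lo + (j - 1) * sj;
            double *pl = S + j * sj;            // k = 0 plane, same j
            for (int i = 1; i <= m; ++i) {
                const int fi = f[i - 1];
                double best = dup[i - 1] + gam3(fi, lj, rk);
                double c = up[i - 1] + gam3(fi, lj, 0);
                if (c > best) best = c;
                c = dlo[i - 1] + sig[fi][rk] + 2.0 * delta;
                if (c > best) best = c;
                c = cur[i - 1] + 2.0 * delta;
                if (c > best) best = c;
                c = dup[i] + g_lr;
                if (c > best) best = c;
                c = up[i] + g_l;
                if (c > best) best = c;
                c = dlo[i] + g_r;
                if (c > best) best = c;
                c = pl[i];                      // free deletion of R[1..k]
                if (c > best) best = c;
                cur[i] = best;
            }
        }
    }

    Sv.attr("dim") = IntegerVector::create(m + 1, n + 1, p + 1);
    return Sv;
}

// Fill the matrix M holding optimal scores of an F-R alignment that
// continues after the end of the aligned part of L, together with the
// prefix-maximum array mtilde[i] = max_{i'<i} max_j S[i',j,0].
// [[Rcpp::export]]
List pla_fill_m(NumericVector Sv, IntegerVector f, IntegerVector r,
                int n, double alpha, double beta, double delta) {
    const int m = f.size(), p = r.size();
    const R_xlen_t d1 = m + 1, d2 = n + 1;
    const double *S = REAL(Sv);
    const R_xlen_t sj = d1, sk = d1 * d2;
    double sig[6][6];
    sigTable(alpha, beta, delta, sig);

    NumericVector mtilde(m + 1);
    mtilde[0] = R_NegInf;
    for (int i = 1; i <= m; ++i) {
        double rowmax = R_NegInf;
        for (int j = 0; j <= n; ++j) {
            double v = S[(i - 1) + j * sj];
            if (v > rowmax) rowmax = v;
        }
        mtilde[i] = (mtilde[i - 1] > rowmax) ? mtilde[i - 1] : rowmax;
    }

    NumericMatrix M(m + 1, p + 1);
    double *Mp = REAL(M);
    for (int k = 0; k <= p; ++k) {
        double *Mc = Mp + (R_xlen_t)k * d1;
        double *Ml = Mp + (R_xlen_t)(k - 1) * d1;
        const double *lev = S + (R_xlen_t)k * sk;
        for (int i = 0; i <= m; ++i) {
            double best = R_NegInf, c;
            if (i >= 1 && k >= 1) {
                c = Ml[i - 1] + sig[f[i - 1]][r[k - 1]];
                if (c > best) best = c;
            }
            if (i >= 1) {
                c = Mc[i - 1] + delta;
                if (c > best) best = c;
            }
            if (k >= 1) {
                c = Ml[i] + delta;
                if (c > best) best = c;
            }
            for (int j = 0; j <= n; ++j) {          // L ends at position j
                c = lev[i + j * sj];
                if (c > best) best = c;
            }
            if (i >= 1 && mtilde[i] > best) best = mtilde[i];  // free interval
            Mc[i] = best;
        }
    }

    return List::create(_["M"] = M, _["mtilde"] = mtilde);
}
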