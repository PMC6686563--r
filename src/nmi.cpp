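#include <Rcpp.h>
using namespace Rcpp;

// Shared kernels for pairwise normalized mutual information on discretized
// expression profiles. Bin indices are 1-based (1..nbins); the R side owns
// the quantile binning rule. All entropies/MI in nats.

static double pair_mi(const int* bx, const int* by, int n, int nbins,
                      std::vector<int>& joint) {
    std::fill(joint.begin(), joint.end(), 0);
    for (int s = 0; s < n; ++s)
        joint[(bx[s] - 1) * nbins + (by[s] - 1)]++;
    std::vector<int> rx(nbins, 0), ry(nbins, 0);
    for (int i = 0; i < nbins; ++i)
        for (int j = 0; j < nbins; ++j) {
            rx[i] += joint[i * nbins + j];
            ry[j] += joint[i * nbins + j];
        }
    double mi = 0.0, dn = (double)n;
    for (int i = 0; i < nbins; ++i) {
        if (rx[i] == 0) continue;
        for (int j = 0; j < nbins; ++j) {
            int c = joint[i * nbins + j];
            if (c == 0 || ry[j] == 0) continue;
            double pij = c / dn;
            mi += pij * std::log(pij * dn * dn / ((double)rx[i] * (double)ry[j]));
        }
    }
    return mi > 0 ? mi : 0.0;
}

static double marg_entropy(const int* b, int n, int nbins) {
    std::vector<int> cnt(nbins, 0);
    for (int s = 0; s < n; ++s) cnt[b[s] - 1]++;
    double h = 0.0, dn = (double)n;
    for (int i = 0; i < nbins; ++i)
        if (cnt[i] > 0) { double p = cnt[i] / dn; h -= p * std::log(p); }
    return h;
}

// All-pairs normalized MI for a genes x samples bin-index matrix.
// Returns a symmetric G x G matrix; normalization by min marginal entropy,
// with 0/0 defined as 0.
// [[Rcpp::export]]
NumericMatrix cpp_nmi_matrix(IntegerMatrix bins, int nbins) {
    int g = bins.nrow(), n = bins.ncol();
    // row-major copy for cache-friendly pair scans
    std::vector<int> bm((size_t)g * n);
    for (int i = 0; i < g; ++i)
        for (int s = 0; s < n; ++s) bm[(size_t)i * n + s] = bins(i, s);
    std::vector<double> ent(g);
    for (int i = 0; i < g; ++i) ent[i] = marg_entropy(&bm[(size_t)i * n], n, nbins);
    NumericMatrix out(g, g);
    std::vector<int> joint(nbins * nbins);
    for (int i = 0; i < g; ++i) {
        out(i, i) = ent[i] > 0 ? 1.0 : 0.0;
        for (int j = i + 1; j < g; ++j) {
            double hmin = std::min(ent[i], ent[j]);
            double v = 0.0;
            if (hmin > 0) {
                double mi = pair_mi(&bm[(size_t)i * n], &bm[(size_t)j * n], n, nbins, joint);
                v = mi / hmin;
                if (v > 1.0) v = 1.0;
            }
            out(i, j) = v;
            out(j, i) = v;
        }
    }
    return out;
}

// Raw MI and marginal entropies for one pair (used by the R-level estimator
// and as the consistency bridge between the R and compiled paths).
// [[Rcpp::export]]
List cpp_pair_mi(IntegerVector bx, IntegerVector by, int nbins) {
    int n = bx.size();
    std::vector<int> joint(nbins * nbins);
    double mi = pair_mi(&bx[0], &by[0], n, nbins, joint);
    return List::create(_["mi"] = mi,
                        _["hx"] = marg_entropy(&bx[0], n, nbins),
                        _["hy"] = marg_entropy(&by[0], n, nbins));
}

// Permutation p-values for candidate pairs (rows of `pairs`, 1-based gene
// indices). Permuting one margin preserves both marginal entropies, so the
// test on raw MI is equivalent to one on normalized MI. Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_perm_pvals(IntegerMatrix bins, int nbins, IntegerMatrix pairs,
                             int nperm) {
    int n = bins.ncol(), np = pairs.nrow();
    NumericVector pv(np);
    std::vector<int> joint(nbins * nbins), bx(n), by(n), perm(n);
    for (int p = 0; p < np; ++p) {
        int gi = pairs(p, 0) - 1, gj = pairs(p, 1) - 1;
        for (int s = 0; s < n; ++s) { bx[s] = bins(gi, s); by[s] = bins(gj, s); }
        double obs = pair_mi(&bx[0], &by[0], n, nbins, joint);
        int ge = 0;
        for (int r = 0; r < nperm; ++r) {
            perm = by;
            // Fisher-Yates with R's RNG for reproducibility under set.seed
            for (int s = n - 1; s > 0; --s) {
                int k = (int)(unif_rand() * (s + 1));
                if (k > s) k = s;
                std::swap(perm[s], perm[k]);
            }
            if (pair_mi(&bx[0], &perm[0], n, nbins, joint) >= obs - 1e-12) ge++;
        }
        pv[p] = (1.0 + ge) / (1.0 + nperm);
    }
    return pv;
}

// Null distribution of normalized MI under independence for equal-frequency
// binning: both margins are random orderings of the fixed balanced label
// multiset implied by the rank rule at sample size n.
// [[Rcpp::export]]
NumericVector cpp_null_nmi(int n, int nbins, int nsim) {
    std::vector<int> base(n);
    for (int s = 0; s < n; ++s) base[s] = (int)(((long long)s * nbins) / n) + 1;
    std::vector<int> bx(n), by(n), joint(nbins * nbins);
    double h = marg_entropy(&base[0], n, nbins);
    NumericVector out(nsim);
    for (int r = 0; r < nsim; ++r) {
        bx = base; by = base;
        for (int s = n - 1; s > 0; --s) {
            int k = (int)(unif_rand() * (s + 1)); if (k > s) k = s;
            std::swap(bx[s], bx[k]);
        }
        for (int s = n - 1; s > 0; --s) {
            int k = (int)(unif_rand() * (s + 1)); if (k > s) k = s;
            std::swap(by[s], by[k]);
        }
        out[r] = h > 0 ? pair_mi(&bx[0], &by[0], n, nbins, joint) / h : 0.0;
    }
    return out;
}
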