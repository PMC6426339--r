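#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation kernels.
//
// An arc of a vector x[0..n) is the index set (i, j] (0-based boundaries,
// 0 <= i < j <= n).  Arcs that wrap around the circle are the complements of
// plain arcs and yield the same |T|, so scanning i < j covers all of them.
// T(i, j) is the pooled-variance two-sample t statistic comparing the mean
// inside the arc against the mean outside.
//
// With W_t = S_t - t*mu (centered partial sums), D = W_j - W_i, k = j - i
// and C = sum(x^2) - n*mu^2 (invariant under permutation of x):
//     u   = D^2 * n / (k * (n - k))
//     T^2 = u / max((C - u) / (n - 2), VAR_FLOOR)
// T^2 is increasing in u, and for fixed k increasing in |D|.  So the max
// scan only needs, per arc width k, the maximal |D|; and the permutation
// test only needs to compare |D| against a per-width threshold derived once
// per test from the observed statistic.  Inner loops are 3-op streaming
// passes over W.

static const double VAR_FLOOR = 1e-12;

static inline double t2_from_u(double u, double C, int df) {
    double s2 = (C - u) / df;
    if (s2 < VAR_FLOOR) s2 = VAR_FLOOR;
    return u / s2;
}

// smallest u with t2_from_u(u, C, df) >= t2 (inverse of the monotone map)
static inline double u_crit_from_t2(double t2, double C, int df) {
    // un-floored branch: u = C * t2 / (df + t2); valid while (C-u)/df >= floor
    double u = C * t2 / (df + t2);
    if ((C - u) / df < VAR_FLOOR) u = t2 * VAR_FLOOR;  // floored branch
    return u;
}

static double center_walk(const double *x, int n, std::vector<double> &W,
                          double &C) {
    double sum = 0.0, sumsq = 0.0;
    for (int t = 0; t < n; ++t) { sum += x[t]; sumsq += x[t] * x[t]; }
    double mu = sum / n;
    C = sumsq - n * mu * mu;
    W[0] = 0.0;
    for (int t = 0; t < n; ++t) W[t + 1] = W[t] + x[t] - mu;
    // exactly zero by construction; forcing it makes the complement arcs
    // (0, i] and (i, n] bitwise-tied so the lexicographic tie-break applies
    W[n] = 0.0;
    return mu;
}

// Exhaustive max-|T| arc scan.  Both the arc and its complement must contain
// at least min_width elements.  Ties resolved to smallest i, then smallest j.
// [[Rcpp::export]]
List cpp_max_arc(NumericVector x, int min_width) {
    int n = x.size();
    if (n < 2 * min_width)
        return List::create(_["i"] = -1, _["j"] = -1, _["stat"] = -1.0);
    std::vector<double> W(n + 1);
    double C;
    center_walk(REAL(x), n, W, C);
    int df = n - 2 > 1 ? n - 2 : 1;
    double best_t2 = -1.0;
    int bi = -1, bj = -1;
    for (int k = min_width; k <= n - min_width; ++k) {
        double bestD = -1.0;
        int besti = -1;
        const double *lo = W.data(), *hi = W.data() + k;
        for (int i = 0; i + k <= n; ++i) {
            double d = std::fabs(hi[i] - lo[i]);
            if (d > bestD) { bestD = d; besti = i; }
        }
        double u = bestD * bestD * n / ((double)k * (n - k));
        double t2 = t2_from_u(u, C, df);
        if (t2 > best_t2 ||
            (t2 == best_t2 && (besti < bi || (besti == bi && besti + k < bj)))) {
            best_t2 = t2; bi = besti; bj = besti + k;
        }
    }
    return List::create(_["i"] = bi, _["j"] = bj,
                        _["stat"] = best_t2 < 0 ? -1.0 : std::sqrt(best_t2));
}

// Does any arc of x reach T^2 >= t2_ref?  W is scratch for the centered
// walk; per width k the comparison reduces to D^2 >= u_crit * k(n-k) / n.
static bool any_arc_exceeds(const double *x, int n, double t2_ref,
                            int min_width, std::vector<double> &W) {
    double C;
    center_walk(x, n, W, C);
    int df = n - 2 > 1 ? n - 2 : 1;
    double u_crit = u_crit_from_t2(t2_ref, C, df);
    // range screen: D^2 <= range^2 for every arc, k(n-k) >= mw*(n-mw)
    double wmax = 0.0, wmin = 0.0;
    for (int t = 1; t <= n; ++t) {
        if (W[t] > wmax) wmax = W[t];
        if (W[t] < wmin) wmin = W[t];
    }
    double range2 = (wmax - wmin) * (wmax - wmin);
    if (range2 * n < u_crit * min_width * (n - min_width)) return false;
    for (int k = min_width; k <= n - min_width; ++k) {
        double d2k = u_crit * k * (n - k) / n;
        if (range2 < d2k) continue;
        const double *lo = W.data(), *hi = W.data() + k;
        for (int i = 0; i + k <= n; ++i) {
            double d = hi[i] - lo[i];
            if (d * d >= d2k) return true;
        }
    }
    return false;
}

// Permutation test for the observed max arc statistic.  Uses R's RNG
// (deterministic under set.seed).  The permutation loop terminates early as
// soon as enough exceedances have accumulated that p >= alpha is guaranteed
// with the +1 correction p = (1 + #exceed) / (1 + n_perm).
// [[Rcpp::export]]
List cpp_perm_test(NumericVector x, double t_obs, int n_perm, double alpha,
                   int min_width) {
    int n = x.size();
    NumericVector y = clone(x);
    std::vector<double> W(n + 1);
    double t2_obs = t_obs * t_obs;
    int stop_at = (int)std::ceil(alpha * (1.0 + n_perm) - 1.0);
    if (stop_at < 1) stop_at = 1;
    int exceed = 0, used = 0;
    bool early = false;
    for (int p = 0; p < n_perm; ++p) {
        for (int t = n - 1; t > 0; --t) {  // Fisher-Yates
            int r = (int)(unif_rand() * (t + 1));
            if (r > t) r = t;
            std::swap(y[t], y[r]);
        }
        ++used;
        if (any_arc_exceeds(REAL(y), n, t2_obs, min_width, W)) {
            if (++exceed >= stop_at) { early = true; break; }
        }
    }
    double pval = early ? 1.0 : (1.0 + exceed) / (1.0 + n_perm);
    return List::create(_["p"] = pval,
                        _["significant"] = (!early) && (pval < alpha),
                        _["n_used"] = used);
}
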