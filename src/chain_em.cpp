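// Core dynamic programming and EM routines for the segment-inclusion
// Markov chain. Segments are indexed 0..M-1 in transcription order;
// boundary b sits between segments b and b+1. btype[b] is 0 for an exon
// start site (parameter p[bpar[b]-1]) and 1 for an exon end site
// (parameter q[bpar[b]-1]).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<std::vector<int> > PatternSet;

// transition matrix T[z][z'] at a boundary.
// start site: 0->1 with prob par, 1->1 always (an ongoing exon ignores it).
// end site:   1->0 with prob par, 0->0 always (an intron ignores it).
static inline void transMat(int type, double par, double T[2][2]) {
    if (type == 0) {
        T[0][0] = 1.0 - par; T[0][1] = par;
        T[1][0] = 0.0;       T[1][1] = 1.0;
    } else {
        T[0][0] = 1.0;       T[0][1] = 0.0;
        T[1][0] = par;       T[1][1] = 1.0 - par;
    }
}

struct ChainSpec {
    std::vector<int> segLen, btype, bpar;
    int M, L;
};

static inline double paramAt(const ChainSpec& cs, int b,
                             const std::vector<double>& p,
                             const std::vector<double>& q) {
    return cs.btype[b] == 0 ? p[cs.bpar[b] - 1] : q[cs.bpar[b] - 1];
}

// Expected effective length D(theta) = sum_Z l(Z) w(Z), l(Z) = max(tl - L + 1, 0).
// DP over (state z, c = min(accumulated transcribed length, L)); buckets with
// c == L additionally carry the aggregated excess mass g = sum prob * (tl - L),
// so D = f0[L] + f1[L] + g0 + g1 at the end (excess + 1 per path with tl >= L).
static double effLenCore(const ChainSpec& cs, double pi,
                         const std::vector<double>& p,
                         const std::vector<double>& q) {
    const int M = cs.M, L = cs.L;
    static std::vector<double> f0, f1, tmp;
    f0.assign(L + 1, 0.0); f1.assign(L + 1, 0.0); tmp.assign(L + 1, 0.0);
    double g0 = 0.0, g1 = 0.0;
    f0[0] = 1.0 - pi;
    {
        long len = cs.segLen[0];
        if (len >= L) { f1[L] = pi; g1 = pi * (double)(len - L); }
        else f1[len] = pi;
    }
    for (int b = 0; b < M - 1; ++b) {
        double T[2][2];
        transMat(cs.btype[b], paramAt(cs, b, p, q), T);
        for (int c = 0; c <= L; ++c) {
            double a = f0[c], bb = f1[c];
            f0[c] = T[0][0] * a + T[1][0] * bb;
            f1[c] = T[0][1] * a + T[1][1] * bb;
        }
        double ga = g0, gb = g1;
        g0 = T[0][0] * ga + T[1][0] * gb;
        g1 = T[0][1] * ga + T[1][1] * gb;
        long len = cs.segLen[b + 1];
        std::fill(tmp.begin(), tmp.end(), 0.0);
        for (int c = 0; c <= L; ++c) {
            if (f1[c] == 0.0) continue;
            long nc = (long)c + len;
            if (nc >= L) { tmp[L] += f1[c]; g1 += f1[c] * (double)(nc - L); }
            else tmp[nc] += f1[c];
        }
        std::swap(f1, tmp);
    }
    return f0[L] + f1[L] + g0 + g1;
}

// log P(Z matches the signature's span pattern): forward marginal at the
// first segment times the forced transition factors along the span.
static double patternLogProbOne(const ChainSpec& cs, double pi,
                                const std::vector<double>& p,
                                const std::vector<double>& q,
                                int first0, const std::vector<int>& pat) {
    double a1 = pi;
    for (int b = 0; b < first0; ++b) {
        double T[2][2];
        transMat(cs.btype[b], paramAt(cs, b, p, q), T);
        a1 = (1.0 - a1) * T[0][1] + a1 * T[1][1];
    }
    double lp = (a1 > 0.0) ? std::log(a1) : R_NegInf;
    for (size_t k = 0; k + 1 < pat.size(); ++k) {
        double T[2][2];
        int b = first0 + (int)k;
        transMat(cs.btype[b], paramAt(cs, b, p, q), T);
        double f = T[pat[k]][pat[k + 1]];
        lp += (f > 0.0) ? std::log(f) : R_NegInf;
    }
    return lp;
}

// Observed-data log-likelihood from signature counts:
// sum_j c_j (log spc_j + log P(pattern_j)) - N log D.
static double loglikCore(const ChainSpec& cs, double pi,
                         const std::vector<double>& p,
                         const std::vector<double>& q,
                         const std::vector<int>& first0,
                         const PatternSet& pats,
                         const std::vector<double>& logspc,
                         const std::vector<double>& counts) {
    double D = effLenCore(cs, pi, p, q);
    if (!(D > 0.0)) return R_NegInf;
    double N = 0.0, ll = 0.0;
    for (size_t j = 0; j < counts.size(); ++j) {
        N += counts[j];
        double lp = patternLogProbOne(cs, pi, p, q, first0[j], pats[j]);
        ll += counts[j] * (logspc[j] + lp);
    }
    return ll - N * std::log(D);
}

// E-step: expected initial-state and boundary-transition counts under the
// posterior over Z given each signature (the chain conditioned on the
// signature's span pattern), weighted by signature counts.
struct ECounts {
    double Api, Bpi;            // E[#(Z1=1)], E[#(Z1=0)]
    std::vector<double> Ap, Bp; // per start site: E[#0->1], E[#0->0]
    std::vector<double> Aq, Bq; // per end site:   E[#1->0], E[#1->1]
};

static void estepCore(const ChainSpec& cs, double pi,
                      const std::vector<double>& p,
                      const std::vector<double>& q,
                      const std::vector<int>& first0,
                      const PatternSet& pats,
                      const std::vector<double>& counts, ECounts& ec) {
    const int M = cs.M;
    ec.Api = ec.Bpi = 0.0;
    ec.Ap.assign(p.size(), 0.0); ec.Bp.assign(p.size(), 0.0);
    ec.Aq.assign(q.size(), 0.0); ec.Bq.assign(q.size(), 0.0);
    static std::vector<double> a0, a1, b0, b1;
    static std::vector<char> al0, al1;
    a0.resize(M); a1.resize(M); b0.resize(M); b1.resize(M);
    al0.resize(M); al1.resize(M);
    for (size_t j = 0; j < counts.size(); ++j) {
        double cj = counts[j];
        if (cj == 0.0) continue;
        const std::vector<int>& pat = pats[j];
        int f0j = first0[j];
        std::fill(al0.begin(), al0.end(), 1);
        std::fill(al1.begin(), al1.end(), 1);
        for (size_t k = 0; k < pat.size(); ++k) {
            if (pat[k] == 1) al0[f0j + k] = 0; else al1[f0j + k] = 0;
        }
        // forward (scaled)
        a0[0] = al0[0] ? (1.0 - pi) : 0.0;
        a1[0] = al1[0] ? pi : 0.0;
        double s = a0[0] + a1[0];
        if (s > 0) { a0[0] /= s; a1[0] /= s; }
        for (int b = 0; b < M - 1; ++b) {
            double T[2][2];
            transMat(cs.btype[b], paramAt(cs, b, p, q), T);
            double n0 = T[0][0] * a0[b] + T[1][0] * a1[b];
            double n1 = T[0][1] * a0[b] + T[1][1] * a1[b];
            if (!al0[b + 1]) n0 = 0.0;
            if (!al1[b + 1]) n1 = 0.0;
            s = n0 + n1;
            if (s > 0) { n0 /= s; n1 /= s; }
            a0[b + 1] = n0; a1[b + 1] = n1;
        }
        // backward (scaled); allow factors of position i+1 enter beta_i
        b0[M - 1] = 1.0; b1[M - 1] = 1.0;
        for (int b = M - 2; b >= 0; --b) {
            double T[2][2];
            transMat(cs.btype[b], paramAt(cs, b, p, q), T);
            double c0 = al0[b + 1] ? b0[b + 1] : 0.0;
            double c1 = al1[b + 1] ? b1[b + 1] : 0.0;
            double n0 = T[0][0] * c0 + T[0][1] * c1;
            double n1 = T[1][0] * c0 + T[1][1] * c1;
            s = n0 + n1;
            if (s > 0) { n0 /= s; n1 /= s; }
            b0[b] = n0; b1[b] = n1;
        }
        // initial state posterior
        double g0 = a0[0] * b0[0], g1 = a1[0] * b1[0];
        s = g0 + g1;
        if (s > 0) { ec.Api += cj * g1 / s; ec.Bpi += cj * g0 / s; }
        // edge posteriors
        for (int b = 0; b < M - 1; ++b) {
            double T[2][2];
            transMat(cs.btype[b], paramAt(cs, b, p, q), T);
            double c0 = al0[b + 1] ? b0[b + 1] : 0.0;
            double c1 = al1[b + 1] ? b1[b + 1] : 0.0;
            double x00 = a0[b] * T[0][0] * c0;
            double x01 = a0[b] * T[0][1] * c1;
            double x10 = a1[b] * T[1][0] * c0;
            double x11 = a1[b] * T[1][1] * c1;
            double xs = x00 + x01 + x10 + x11;
            if (xs <= 0.0) continue;
            int m = cs.bpar[b] - 1;
            if (cs.btype[b] == 0) {
                ec.Ap[m] += cj * x01 / xs;
                ec.Bp[m] += cj * x00 / xs;
            } else {
                ec.Aq[m] += cj * x10 / xs;
                ec.Bq[m] += cj * x11 / xs;
            }
        }
    }
}

// One-dimensional exact maximization of
//   h(t) = A log t + B log(1-t) - N log(alpha + beta t)
// on [eps, 1-eps]. D(theta) is linear in each individual parameter, so
// alpha, beta come from two effLenCore evaluations; stationary points of h
// are roots of a quadratic.
static double maximizeParam(double A, double B, double N,
                            double alpha, double beta,
                            double tcur, double eps) {
    double cand[5];
    int ncand = 0;
    cand[ncand++] = tcur;
    cand[ncand++] = eps;
    cand[ncand++] = 1.0 - eps;
    double a2 = beta * (N - A - B);
    double a1 = A * beta - (A + B) * alpha - N * beta;
    double a0 = A * alpha;
    double scale = std::max(std::fabs(a2),
                            std::max(std::fabs(a1), std::fabs(a0)));
    if (scale > 0.0) {
        double r2 = a2 / scale, r1 = a1 / scale, r0 = a0 / scale;
        if (std::fabs(r2) < 1e-14) {
            if (std::fabs(r1) > 1e-14) cand[ncand++] = -r0 / r1;
        } else {
            double disc = r1 * r1 - 4.0 * r2 * r0;
            if (disc >= 0.0) {
                double sq = std::sqrt(disc);
                double qq = -0.5 * (r1 + (r1 >= 0 ? sq : -sq));
                if (qq != 0.0) { cand[ncand++] = qq / r2; cand[ncand++] = r0 / qq; }
            }
        }
    }
    double best = tcur, hbest = R_NegInf;
    for (int i = 0; i < ncand; ++i) {
        double t = cand[i];
        if (!(t >= eps && t <= 1.0 - eps)) continue;
        double den = alpha + beta * t;
        if (!(den > 0.0)) continue;
        double h = -N * std::log(den);
        if (A > 0.0) h += A * std::log(t);
        if (B > 0.0) h += B * std::log(1.0 - t);
        if (h > hbest + 1e-14 || (i == 0 && h > hbest)) { hbest = h; best = t; }
    }
    return best;
}

// ---- conversion helpers for the exported wrappers ----

static ChainSpec makeSpec(const IntegerVector& segLen,
                          const IntegerVector& btype,
                          const IntegerVector& bpar, int L) {
    ChainSpec cs;
    cs.segLen.assign(segLen.begin(), segLen.end());
    cs.btype.assign(btype.begin(), btype.end());
    cs.bpar.assign(bpar.begin(), bpar.end());
    cs.M = cs.segLen.size();
    cs.L = L;
    return cs;
}

static void makeSignatures(const IntegerVector& sigFirst,
                           const List& sigPattern,
                           std::vector<int>& first0, PatternSet& pats) {
    int J = sigFirst.size();
    first0.resize(J);
    pats.resize(J);
    for (int j = 0; j < J; ++j) {
        first0[j] = sigFirst[j] - 1;
        IntegerVector pat = sigPattern[j];
        pats[j].assign(pat.begin(), pat.end());
    }
}

// [[Rcpp::export]]
double cpp_expected_eff_len(double pi, NumericVector p, NumericVector q,
                            IntegerVector segLen, IntegerVector btype,
                            IntegerVector bpar, int L) {
    ChainSpec cs = makeSpec(segLen, btype, bpar, L);
    std::vector<double> pv(p.begin(), p.end()), qv(q.begin(), q.end());
    return effLenCore(cs, pi, pv, qv);
}

// P(Z_i = 1) for i = 1..M by the forward recursion.
// [[Rcpp::export]]
NumericVector cpp_forward_marginals(double pi, NumericVector p, NumericVector q,
                                    IntegerVector btype, IntegerVector bpar) {
    ChainSpec cs = makeSpec(IntegerVector(btype.size() + 1, 1),
                            btype, bpar, 1);
    std::vector<double> pv(p.begin(), p.end()), qv(q.begin(), q.end());
    const int M = btype.size() + 1;
    NumericVector m(M);
    double a1 = pi;
    m[0] = a1;
    for (int b = 0; b < M - 1; ++b) {
        double T[2][2];
        transMat(cs.btype[b], paramAt(cs, b, pv, qv), T);
        a1 = (1.0 - a1) * T[0][1] + a1 * T[1][1];
        m[b + 1] = a1;
    }
    return m;
}

// [[Rcpp::export]]
NumericVector cpp_pattern_logprob(double pi, NumericVector p, NumericVector q,
                                  IntegerVector btype, IntegerVector bpar,
                                  IntegerVector sigFirst, List sigPattern) {
    ChainSpec cs = makeSpec(IntegerVector(btype.size() + 1, 1),
                            btype, bpar, 1);
    std::vector<double> pv(p.begin(), p.end()), qv(q.begin(), q.end());
    std::vector<int> first0;
    PatternSet pats;
    makeSignatures(sigFirst, sigPattern, first0, pats);
    NumericVector out(first0.size());
    for (size_t j = 0; j < first0.size(); ++j)
        out[j] = patternLogProbOne(cs, pi, pv, qv, first0[j], pats[j]);
    return out;
}

// [[Rcpp::export]]
double cpp_loglik(double pi, NumericVector p, NumericVector q,
                  IntegerVector segLen, IntegerVector btype, IntegerVector bpar,
                  int L, IntegerVector sigFirst, List sigPattern,
                  NumericVector logspc, NumericVector counts) {
    ChainSpec cs = makeSpec(segLen, btype, bpar, L);
    std::vector<double> pv(p.begin(), p.end()), qv(q.begin(), q.end());
    std::vector<int> first0;
    PatternSet pats;
    makeSignatures(sigFirst, sigPattern, first0, pats);
    std::vector<double> ls(logspc.begin(), logspc.end());
    std::vector<double> cv(counts.begin(), counts.end());
    return loglikCore(cs, pi, pv, qv, first0, pats, ls, cv);
}

// [[Rcpp::export]]
List cpp_em_fit(double pi0, NumericVector p0, NumericVector q0,
                IntegerVector segLen, IntegerVector btype, IntegerVector bpar,
                int L, IntegerVector sigFirst, List sigPattern,
                NumericVector logspc, NumericVector counts,
                double tol, int maxIter) {
    const double eps = 1e-9;
    ChainSpec cs = makeSpec(segLen, btype, bpar, L);
    std::vector<int> first0;
    PatternSet pats;
    makeSignatures(sigFirst, sigPattern, first0, pats);
    std::vector<double> ls(logspc.begin(), logspc.end());
    std::vector<double> cv(counts.begin(), counts.end());

    double pi = std::min(std::max(pi0, eps), 1.0 - eps);
    std::vector<double> p(p0.begin(), p0.end()), q(q0.begin(), q0.end());
    for (size_t i = 0; i < p.size(); ++i)
        p[i] = std::min(std::max(p[i], eps), 1.0 - eps);
    for (size_t i = 0; i < q.size(); ++i)
        q[i] = std::min(std::max(q[i], eps), 1.0 - eps);
    double N = 0.0;
    for (size_t j = 0; j < cv.size(); ++j) N += cv[j];

    std::vector<double> trace;
    double ll = loglikCore(cs, pi, p, q, first0, pats, ls, cv);
    trace.push_back(ll);
    bool converged = false;
    int it = 0;
    ECounts ec;
    for (it = 1; it <= maxIter; ++it) {
        if (!R_finite(ll)) break;
        estepCore(cs, pi, p, q, first0, pats, cv, ec);
        // conditional maximizations; D is re-linearized at the current theta
        {
            double hold = pi;
            double d0 = effLenCore(cs, 0.0, p, q);
            double d1 = effLenCore(cs, 1.0, p, q);
            pi = maximizeParam(ec.Api, ec.Bpi, N, d0, d1 - d0, hold, eps);
        }
        for (size_t m = 0; m < p.size(); ++m) {
            double hold = p[m];
            p[m] = 0.0; double d0 = effLenCore(cs, pi, p, q);
            p[m] = 1.0; double d1 = effLenCore(cs, pi, p, q);
            p[m] = maximizeParam(ec.Ap[m], ec.Bp[m], N, d0, d1 - d0,
                                 hold, eps);
        }
        for (size_t m = 0; m < q.size(); ++m) {
            double hold = q[m];
            q[m] = 0.0; double d0 = effLenCore(cs, pi, p, q);
            q[m] = 1.0; double d1 = effLenCore(cs, pi, p, q);
            q[m] = maximizeParam(ec.Aq[m], ec.Bq[m], N, d0, d1 - d0,
                                 hold, eps);
        }
        double llnew = loglikCore(cs, pi, p, q, first0, pats, ls, cv);
        trace.push_back(llnew);
        double rel = std::fabs(llnew - ll) / (std::fabs(ll) + 1e-10);
        ll = llnew;
        if (rel < tol) { converged = true; break; }
    }
    return List::create(_["pi"] = pi,
                        _["p"] = NumericVector(p.begin(), p.end()),
                        _["q"] = NumericVector(q.begin(), q.end()),
                        _["trace"] = NumericVector(trace.begin(), trace.end()),
                        _["iterations"] = std::min(it, maxIter),
                        _["converged"] = converged,
                        _["logLik"] = ll);
}
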