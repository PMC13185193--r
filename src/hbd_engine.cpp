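// Batched scaled forward-backward for the multi-class HBD hidden Markov
// model. All HBD classes share one emission law and the non-HBD class
// another, so emissions enter as two markers x samples matrices. The
// transition between adjacent markers at genetic distance d is
//   T_kj = exp(-R_k d) * delta_kj + (1 - exp(-R_k d)) * M_j
// with a per-sample mixing matrix M. Chromosomes are independent chains
// (blocks). Returns per-sample log-likelihoods, posterior state occupancy
// sums, the EM statistics for the mixing update (expected class
// memberships of segment starts), and optionally the full per-marker
// posterior for single-sample calls.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".hbdEngineCpp")]]
List hbdEngineCpp(NumericMatrix eH, NumericMatrix eN, NumericVector rates,
                  NumericMatrix M, NumericVector dist,
                  IntegerVector blockStart, IntegerVector blockLen,
                  bool keepPosterior) {
  const int n = eH.nrow(), S = eH.ncol(), K = rates.size();
  const int nb = blockStart.size();

  NumericVector loglik(S);
  NumericMatrix occ(K, S), resetStats(K, S);
  NumericMatrix post;
  if (keepPosterior) post = NumericMatrix(n, K);

  std::vector<double> A;      // stored scaled forward, K*S per marker
  std::vector<double> Cs, resetF, at;

  for (int b = 0; b < nb; ++b) {
    const int o = blockStart[b], L = blockLen[b];
    A.assign((size_t)L * K * S, 0.0);
    Cs.assign((size_t)L * S, 0.0);
    resetF.assign((size_t)L * S, 0.0);
    at.assign((size_t)(L > 1 ? L - 1 : 0) * K, 0.0);
    for (int t = 0; t + 1 < L; ++t)
      for (int k = 0; k < K; ++k)
        at[(size_t)t * K + k] = std::exp(-rates[k] * dist[o + t]);

    // forward
    for (int s = 0; s < S; ++s) {
      double *as = &A[(size_t)0 + (size_t)s * K];
      double cs = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = (k < K - 1) ? eH(o, s) : eN(o, s);
        as[k] = M(k, s) * e;
        cs += as[k];
      }
      if (!(cs > 0.0) || !std::isfinite(cs))
        stop("non-finite likelihood (zero emission mass); check inputs");
      for (int k = 0; k < K; ++k) as[k] /= cs;
      Cs[(size_t)s] = cs;
    }
    for (int t = 1; t < L; ++t) {
      const double *a = &at[(size_t)(t - 1) * K];
      for (int s = 0; s < S; ++s) {
        const double *prev = &A[((size_t)(t - 1) * S + s) * K];
        double *cur = &A[((size_t)t * S + s) * K];
        double rm = 0.0;
        for (int k = 0; k < K; ++k) rm += (1.0 - a[k]) * prev[k];
        resetF[(size_t)t * S + s] = rm;
        double cs = 0.0;
        const double ehts = eH(o + t, s), ents = eN(o + t, s);
        for (int k = 0; k < K; ++k) {
          double e = (k < K - 1) ? ehts : ents;
          cur[k] = (a[k] * prev[k] + M(k, s) * rm) * e;
          cs += cur[k];
        }
        if (!(cs > 0.0) || !std::isfinite(cs))
          stop("non-finite likelihood (zero emission mass); check inputs");
        for (int k = 0; k < K; ++k) cur[k] /= cs;
        Cs[(size_t)t * S + s] = cs;
      }
    }
    for (int s = 0; s < S; ++s) {
      double ll = 0.0;
      for (int t = 0; t < L; ++t) ll += std::log(Cs[(size_t)t * S + s]);
      loglik[s] += ll;
    }

    // backward, with gamma accumulation and EM reset statistics
    std::vector<double> be((size_t)K * S, 1.0), eb((size_t)K, 0.0),
        g((size_t)K, 0.0);
    for (int s = 0; s < S; ++s) {
      const double *al = &A[((size_t)(L - 1) * S + s) * K];
      double gs = 0.0;
      for (int k = 0; k < K; ++k) { g[k] = al[k]; gs += g[k]; }
      for (int k = 0; k < K; ++k) {
        occ(k, s) += g[k] / gs;
        if (keepPosterior) post(o + L - 1, k) = g[k] / gs;
      }
    }
    for (int t = L - 2; t >= 0; --t) {
      const double *a = &at[(size_t)t * K];
      for (int s = 0; s < S; ++s) {
        double *bs = &be[(size_t)s * K];
        const double ehts = eH(o + t + 1, s), ents = eN(o + t + 1, s);
        double mcb = 0.0;
        for (int k = 0; k < K; ++k) {
          eb[k] = ((k < K - 1) ? ehts : ents) * bs[k];
          mcb += M(k, s) * eb[k];
        }
        const double cinv = 1.0 / Cs[(size_t)(t + 1) * S + s];
        const double rf = resetF[(size_t)(t + 1) * S + s] * cinv;
        for (int k = 0; k < K; ++k)
          resetStats(k, s) += M(k, s) * eb[k] * rf;
        for (int k = 0; k < K; ++k)
          bs[k] = (a[k] * eb[k] + (1.0 - a[k]) * mcb) * cinv;
        const double *al = &A[((size_t)t * S + s) * K];
        double gs = 0.0;
        for (int k = 0; k < K; ++k) { g[k] = al[k] * bs[k]; gs += g[k]; }
        for (int k = 0; k < K; ++k) {
          occ(k, s) += g[k] / gs;
          if (keepPosterior) post(o + t, k) = g[k] / gs;
        }
      }
    }
    // the initial draw of each chromosome chain is also from M
    for (int s = 0; s < S; ++s) {
      const double *al = &A[(size_t)s * K];
      const double *bs = &be[(size_t)s * K];
      double gs = 0.0;
      for (int k = 0; k < K; ++k) gs += al[k] * bs[k];
      for (int k = 0; k < K; ++k)
        resetStats(k, s) += al[k] * bs[k] / gs;
    }
  }

  List out = List::create(_["loglik"] = loglik, _["occ"] = occ,
                          _["resetStats"] = resetStats);
  if (keepPosterior) out["posterior"] = post;
  return out;
}
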