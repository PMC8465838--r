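#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Plug-in Transfer Entropy with local excitatory/inhibitory decomposition
// for every ordered pair of a binary raster, computed jointly for a nested
// family of ROI masks.
//
// State coding for a tuple at time n (0-based):
//   bit 0                 : x_n (target, current bin)
//   bits 1 .. kx          : x_{n-1}, ..., x_{n-kx}
//   bits kx+1 .. kx+ky    : y_{n-d}, ..., y_{n-d-ky+1}
//
// ROI masks are nested: mask_l = { n : level_idx[n] <= l }, l = 1..L, where
// level_idx[n] is the smallest ROI level whose threshold the network-average
// trace at bin n falls below (L+1 if none). Counts are histogrammed by
// level and cumulated, so the full sweep costs one pass over time per pair.
//
// Each summand  P(s) * log2( P(xn | xpast, ypast) / P(xn | xpast) )  is
// routed to the excitatory component when OR(ypast) == xn and to the
// inhibitory component otherwise.

static inline double te_from_counts(const std::vector<double> &cnt, int kx,
                                    int ky, double &teE, double &teI) {
  const int S = 1 << (1 + kx + ky);
  const int Sxp = 1 << (kx + ky);      // (xpast, ypast) joint
  const int maskx = (1 << (kx + 1)) - 1;
  std::vector<double> n_xyp(Sxp, 0.0);           // N(xpast, ypast)
  std::vector<double> n_xxp(1 << (kx + 1), 0.0); // N(xn, xpast)
  std::vector<double> n_xp(1 << kx, 0.0);        // N(xpast)
  double tot = 0.0;
  for (int s = 0; s < S; ++s) {
    const double c = cnt[s];
    if (c == 0.0) continue;
    tot += c;
    n_xyp[s >> 1] += c;
    n_xxp[s & maskx] += c;
    n_xp[(s & maskx) >> 1] += c;
  }
  teE = 0.0;
  teI = 0.0;
  if (tot == 0.0) return NA_REAL;
  const double l2 = std::log(2.0);
  for (int s = 0; s < S; ++s) {
    const double c = cnt[s];
    if (c == 0.0) continue;
    const double p_cond_joint = c / n_xyp[s >> 1];
    const double p_cond_self = n_xxp[s & maskx] / n_xp[(s & maskx) >> 1];
    const double term = (c / tot) * std::log(p_cond_joint / p_cond_self) / l2;
    const int xn = s & 1;
    const int y_active = ((s >> (kx + 1)) != 0) ? 1 : 0;
    if (y_active == xn) teE += term; else teI += term;
  }
  return teE + teI;
}

// [[Rcpp::export]]
List te_local_pairs_cpp(const IntegerMatrix raster, int kx, int ky, int d,
                        const IntegerVector level_idx, int L) {
  const int N = raster.nrow();
  const int T = raster.ncol();
  const int n0 = std::max(kx, d + ky - 1);
  if (T <= n0) stop("raster too short for the requested embedding");
  if (level_idx.size() != T) stop("level_idx length must equal n bins");
  const int S = 1 << (1 + kx + ky);

  NumericVector teT(N * N * L, NA_REAL), teE(N * N * L, NA_REAL),
      teI(N * N * L, NA_REAL);
  NumericVector n_samples(L, 0.0);
  for (int l = 0; l < L; ++l) {
    double m = 0.0;
    for (int nn = n0; nn < T; ++nn)
      if (level_idx[nn] <= l + 1) m += 1.0;
    n_samples[l] = m;
  }

  std::vector<std::vector<double>> cnt(L + 1, std::vector<double>(S));
  std::vector<double> cum(S);

  for (int j = 0; j < N; ++j) {          // source
    for (int i = 0; i < N; ++i) {        // target
      if (i == j) continue;
      for (int l = 0; l <= L; ++l) std::fill(cnt[l].begin(), cnt[l].end(), 0.0);
      for (int nn = n0; nn < T; ++nn) {
        const int lev = level_idx[nn];
        if (lev < 1 || lev > L) continue;  // NA level index never counted
        int code = raster(i, nn);
        for (int q = 1; q <= kx; ++q) code |= raster(i, nn - q) << q;
        for (int q = 0; q < ky; ++q) code |= raster(j, nn - d - q) << (kx + 1 + q);
        cnt[lev - 1][code] += 1.0;
      }
      std::fill(cum.begin(), cum.end(), 0.0);
      for (int l = 0; l < L; ++l) {
        for (int s = 0; s < S; ++s) cum[s] += cnt[l][s];
        double e, ii;
        const double tt = te_from_counts(cum, kx, ky, e, ii);
        const long idx = (long)l * N * N + (long)j * N + i;
        teT[idx] = tt;
        teE[idx] = R_IsNA(tt) ? NA_REAL : e;
        teI[idx] = R_IsNA(tt) ? NA_REAL : ii;
      }
    }
  }
  teT.attr("dim") = IntegerVector::create(N, N, L);
  teE.attr("dim") = IntegerVector::create(N, N, L);
  teI.attr("dim") = IntegerVector::create(N, N, L);
  return List::create(_["te_total"] = teT, _["te_E"] = teE, _["te_I"] = teI,
                      _["n_samples"] = n_samples);
}
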