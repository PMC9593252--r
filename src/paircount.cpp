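#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bin index for distance d given strictly increasing edges; bins are
// (edges[k], edges[k+1]], k = 0..K-1. Returns -1 when d falls outside.
static inline int find_bin(double d, const double* edges, int K) {
  if (d <= edges[0] || d > edges[K]) return -1;
  const double* pos = std::lower_bound(edges, edges + K + 1, d);
  return static_cast<int>(pos - edges) - 1;
}

// Per-bin sums of pair weights for a single pattern, ordered pairs (i != j).
// mode: 0 = no edge correction, 1 = periodic (torus min-image),
//       2 = translation correction, weight 1/((wx-|dx|)(wy-|dy|)).
// [[Rcpp::export]]
NumericVector pair_weights_uni(NumericVector x, NumericVector y,
                               NumericVector edges, double wx, double wy,
                               int mode) {
  const int n = x.size();
  const int K = edges.size() - 1;
  NumericVector out(K);
  const double rmax = edges[K];
  const double* e = edges.begin();
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = std::fabs(xi - x[j]);
      double dy = std::fabs(yi - y[j]);
      const double edx = dx, edy = dy;  // Euclidean offsets for the weight
      if (mode == 1) {
        if (wx - dx < dx) dx = wx - dx;
        if (wy - dy < dy) dy = wy - dy;
      }
      if (dx > rmax || dy > rmax) continue;
      const int b = find_bin(std::sqrt(dx * dx + dy * dy), e, K);
      if (b < 0) continue;
      double w = 2.0;  // both ordered pairs (i,j) and (j,i)
      if (mode == 2) w = 2.0 / ((wx - edx) * (wy - edy));
      out[b] += w;
    }
  }
  return out;
}

// Per-bin sums of pair weights across two patterns, all ordered pairs
// (a_i, b_j). Coincident pairs (d = 0) fall below the first edge when
// edges[0] == 0 and are therefore never binned.
// [[Rcpp::export]]
NumericVector pair_weights_bi(NumericVector x1, NumericVector y1,
                              NumericVector x2, NumericVector y2,
                              NumericVector edges, double wx, double wy,
                              int mode) {
  const int n1 = x1.size(), n2 = x2.size();
  const int K = edges.size() - 1;
  NumericVector out(K);
  const double rmax = edges[K];
  const double* e = edges.begin();
  for (int i = 0; i < n1; ++i) {
    const double xi = x1[i], yi = y1[i];
    for (int j = 0; j < n2; ++j) {
      double dx = std::fabs(xi - x2[j]);
      double dy = std::fabs(yi - y2[j]);
      const double edx = dx, edy = dy;
      if (mode == 1) {
        if (wx - dx < dx) dx = wx - dx;
        if (wy - dy < dy) dy = wy - dy;
      }
      if (dx > rmax || dy > rmax) continue;
      const int b = find_bin(std::sqrt(dx * dx + dy * dy), e, K);
      if (b < 0) continue;
      double w = 1.0;
      if (mode == 2) w = 1.0 / ((wx - edx) * (wy - edy));
      out[b] += w;
    }
  }
  return out;
}

// Cumulative neighbor counts within each radius for every reference point,
// plus the nearest-neighbor distance to the target set. Used by CBC.
// Returns an (n_ref x n_radii) count matrix and an n_ref vector of
// nearest-target distances (Inf when the target set is empty).
// [[Rcpp::export]]
List ring_counts(NumericVector xr, NumericVector yr,
                 NumericVector xt, NumericVector yt,
                 NumericVector radii) {
  const int nr = xr.size(), nt = xt.size(), nk = radii.size();
  IntegerMatrix counts(nr, nk);
  NumericVector nnd(nr);
  const double rmax = radii[nk - 1];
  for (int i = 0; i < nr; ++i) {
    const double xi = xr[i], yi = yr[i];
    double best = R_PosInf;
    for (int j = 0; j < nt; ++j) {
      const double dx = xi - xt[j], dy = yi - yt[j];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d < best) best = d;
      if (d > rmax) continue;
      // first radius >= d; count point in that ring and all larger ones
      const double* pos = std::lower_bound(radii.begin(), radii.end(), d);
      for (int k = static_cast<int>(pos - radii.begin()); k < nk; ++k)
        counts(i, k) += 1;
    }
    nnd[i] = best;
  }
  return List::create(_["counts"] = counts, _["nnd"] = nnd);
}
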