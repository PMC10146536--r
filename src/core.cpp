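#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement for one component: result in [-L/2, L/2).
static inline double mic1(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

static inline double mic_dist2(const NumericMatrix &A, int i,
                               const NumericMatrix &B, int j,
                               const double *box) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = mic1(A(i, k) - B(j, k), box[k]);
    s += d * d;
  }
  return s;
}

// Count, for every row of `centers`, the rows of `pts` with minimum-image
// distance < cutoff (inclusive = FALSE) or <= cutoff (inclusive = TRUE).
// Pairs at exactly zero distance are skipped (self pairs when groups overlap).
// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericMatrix centers, NumericMatrix pts,
                               NumericVector box, double cutoff,
                               bool inclusive = false) {
  int m = centers.nrow(), p = pts.nrow();
  double b[3] = {box[0], box[1], box[2]};
  double c2 = cutoff * cutoff;
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) {
    int n = 0;
    for (int j = 0; j < p; ++j) {
      double d2 = mic_dist2(centers, i, pts, j, b);
      if (d2 < 1e-24) continue;
      if (inclusive ? (d2 <= c2) : (d2 < c2)) ++n;
    }
    out[i] = n;
  }
  return out;
}

// Minimum-image distance from each row of `pts` to the nearest row of `ref`.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix pts, NumericMatrix ref,
                           NumericVector box) {
  int p = pts.nrow(), r = ref.nrow();
  double b[3] = {box[0], box[1], box[2]};
  NumericVector out(p);
  for (int i = 0; i < p; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < r; ++j) {
      double d2 = mic_dist2(pts, i, ref, j, b);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Minimum surface clearance from each row of `pts` to the spheres
// (ref rows, radii): min_j (dist(pt, ref_j) - radii_j).
// [[Rcpp::export]]
NumericVector cpp_min_clearance(NumericMatrix pts, NumericMatrix ref,
                                NumericVector box, NumericVector radii) {
  int p = pts.nrow(), r = ref.nrow();
  double b[3] = {box[0], box[1], box[2]};
  NumericVector out(p);
  for (int i = 0; i < p; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < r; ++j) {
      double c = std::sqrt(mic_dist2(pts, i, ref, j, b)) - radii[j];
      if (c < best) best = c;
    }
    out[i] = best;
  }
  return out;
}

// Histogram of minimum-image center->point distances into nbins half-open
// bins [k*dr, (k+1)*dr) with dr = rmax/nbins. Zero-distance pairs skipped.
// [[Rcpp::export]]
NumericVector cpp_dist_hist(NumericMatrix centers, NumericMatrix pts,
                            NumericVector box, double rmax, int nbins) {
  double b[3] = {box[0], box[1], box[2]};
  double dr = rmax / nbins;
  NumericVector out(nbins);
  int m = centers.nrow(), p = pts.nrow();
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < p; ++j) {
      double d2 = mic_dist2(centers, i, pts, j, b);
      if (d2 < 1e-24) continue;
      double d = std::sqrt(d2);
      if (d >= rmax) continue;
      int k = (int)(d / dr);
      if (k >= nbins) k = nbins - 1;
      out[k] += 1.0;
    }
  return out;
}

// All (i, j) pairs with minimum-image distance <= cutoff (1-based indices).
// When `self` is TRUE the two matrices are the same set and only i < j pairs
// are returned.
// [[Rcpp::export]]
List cpp_pairs_within(NumericMatrix A, NumericMatrix B, NumericVector box,
                      double cutoff, bool self = false) {
  double b[3] = {box[0], box[1], box[2]};
  double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  std::vector<double> dd;
  int m = A.nrow(), p = B.nrow();
  for (int i = 0; i < m; ++i) {
    int j0 = self ? i + 1 : 0;
    for (int j = j0; j < p; ++j) {
      double d2 = mic_dist2(A, i, B, j, b);
      if (d2 <= c2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["d"] = wrap(dd));
}

// Shrake-Rupley accessible area per atom on a deterministic point set.
// Neighbour search uses a uniform cell grid (cell edge = largest augmented
// diameter) so candidate gathering is linear in N for bounded density,
// realising the accessible-surface definition of the rolling 1.4 A probe.
// Positions/radii in nm; returns per-atom areas in nm^2. No periodicity:
// the micelle is analysed unwrapped and isolated.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix pos, NumericVector radii, double probe,
                       NumericMatrix pts) {
  int n = pos.nrow(), K = pts.nrow();
  NumericVector area(n);
  if (n == 0) return area;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i)
    if (radii[i] > rmax) rmax = radii[i];
  double cell = 2.0 * (rmax + probe) + 1e-9;
  double lo[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = pos(0, k);
    for (int i = 1; i < n; ++i)
      if (pos(i, k) < lo[k]) lo[k] = pos(i, k);
  }
  std::unordered_map<long long, std::vector<int> > grid;
  std::vector<long long> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (long long)((pos(i, 0) - lo[0]) / cell);
    cy[i] = (long long)((pos(i, 1) - lo[1]) / cell);
    cz[i] = (long long)((pos(i, 2) - lo[2]) / cell);
    long long key = (cx[i] * 1048576LL + cy[i]) * 1048576LL + cz[i];
    grid[key].push_back(i);
  }
  std::vector<int> nbr;
  std::vector<double> nx, ny, nz, nr2;
  for (int i = 0; i < n; ++i) {
    nbr.clear(); nx.clear(); ny.clear(); nz.clear(); nr2.clear();
    double Ri = radii[i] + probe;
    for (long long ax = cx[i] - 1; ax <= cx[i] + 1; ++ax)
      for (long long ay = cy[i] - 1; ay <= cy[i] + 1; ++ay)
        for (long long az = cz[i] - 1; az <= cz[i] + 1; ++az) {
          long long key = (ax * 1048576LL + ay) * 1048576LL + az;
          std::unordered_map<long long, std::vector<int> >::iterator it =
              grid.find(key);
          if (it == grid.end()) continue;
          const std::vector<int> &cands = it->second;
          for (size_t q = 0; q < cands.size(); ++q) {
            int j = cands[q];
            if (j == i) continue;
            double dx = pos(j, 0) - pos(i, 0);
            double dy = pos(j, 1) - pos(i, 1);
            double dz = pos(j, 2) - pos(i, 2);
            double Rj = radii[j] + probe;
            double reach = Ri + Rj;
            if (dx * dx + dy * dy + dz * dz < reach * reach) {
              nbr.push_back(j);
              nx.push_back(dx); ny.push_back(dy); nz.push_back(dz);
              nr2.push_back(Rj * Rj);
            }
          }
        }
    int nacc = 0;
    size_t nn = nbr.size();
    for (int k = 0; k < K; ++k) {
      double px = Ri * pts(k, 0), py = Ri * pts(k, 1), pz = Ri * pts(k, 2);
      bool buried = false;
      for (size_t q = 0; q < nn; ++q) {
        double dx = px - nx[q], dy = py - ny[q], dz = pz - nz[q];
        if (dx * dx + dy * dy + dz * dz < nr2[q]) { buried = true; break; }
      }
      if (!buried) ++nacc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)nacc / (double)K;
  }
  return area;
}

// <h(t0) h(t0+L)> averaged over pairs (rows of H) and strided time origins,
// one value per requested lag (lags in frames, 0-based).
// [[Rcpp::export]]
NumericVector cpp_lag_corr(NumericMatrix H, IntegerVector lags, int stride) {
  int np = H.nrow(), T = H.ncol(), nl = lags.size();
  NumericVector out(nl);
  for (int l = 0; l < nl; ++l) {
    int L = lags[l];
    double s = 0.0;
    long norig = 0;
    for (int t0 = 0; t0 + L < T; t0 += stride) {
      for (int p = 0; p < np; ++p) s += H(p, t0) * H(p, t0 + L);
      ++norig;
    }
    out[l] = (norig > 0) ? s / ((double)norig * (double)np) : NA_REAL;
  }
  return out;
}
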