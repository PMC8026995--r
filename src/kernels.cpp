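#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Indices 0..M-1 ordered by x value, used to enumerate only candidate pairs
// whose first template coordinates are within r of each other.
static std::vector<int> order_by_value(NumericVector x, int M) {
  std::vector<int> idx(M);
  for (int i = 0; i < M; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  return idx;
}

// Mean log fraction of Chebyshev r-neighbourhood template matches of length m,
// self-matches included (the Pincus phi^m statistic, natural log).
// [[Rcpp::export]]
double cf_apen_phi(NumericVector x, int m, double r) {
  int N = x.size();
  int M = N - m + 1;
  std::vector<int> cnt(M, 1);  // self-match
  std::vector<int> idx = order_by_value(x, M);
  for (int p = 0; p < M - 1; ++p) {
    int i = idx[p];
    double xi = x[i];
    for (int q = p + 1; q < M; ++q) {
      int j = idx[q];
      if (x[j] - xi > r) break;
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (ok) { ++cnt[i]; ++cnt[j]; }
    }
  }
  long double acc = 0.0;
  for (int i = 0; i < M; ++i)
    acc += std::log((double)cnt[i] / (double)M);
  return (double)(acc / M);
}

// Template-pair counts for sample entropy: B = pairs (i<j) whose length-m
// templates match within Chebyshev r, A = pairs whose length-(m+1) templates
// also match. Templates indexed 1..N-m so every one can be extended.
// [[Rcpp::export]]
NumericVector cf_sampen_counts(NumericVector x, int m, double r) {
  int N = x.size();
  int Nm = N - m;
  long double A = 0.0, B = 0.0;
  std::vector<int> idx = order_by_value(x, Nm);
  for (int p = 0; p < Nm - 1; ++p) {
    int i = idx[p];
    double xi = x[i];
    for (int q = p + 1; q < Nm; ++q) {
      int j = idx[q];
      if (x[j] - xi > r) break;
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create((double)A, (double)B);
}

// Rosenstein mean log-divergence curve. For each point the nearest Euclidean
// neighbour outside the Theiler window is tracked for nsteps steps; curve[k]
// is the mean natural-log distance over pairs still inside the attractor.
// [[Rcpp::export]]
List cf_divergence(NumericMatrix a, int theiler, int nsteps) {
  int M = a.nrow(), m = a.ncol();
  // only points trackable for the full nsteps, so the averaged pair set is
  // identical at every step (no composition drift in the curve)
  int Mu = M - nsteps;
  if (Mu < 2) return List::create(_["curve"] = NumericVector(nsteps + 1, NA_REAL),
                                  _["n_pairs"] = IntegerVector(nsteps + 1, 0));
  // attractor scale, for the machine-noise distance floor (exact revisits
  // of a noiseless orbit otherwise dominate the log-distance averages)
  std::vector<double> cen(m, 0.0);
  for (int i = 0; i < M; ++i)
    for (int k = 0; k < m; ++k) cen[k] += a(i, k);
  for (int k = 0; k < m; ++k) cen[k] /= M;
  long double msq = 0.0;
  for (int i = 0; i < M; ++i)
    for (int k = 0; k < m; ++k) {
      double dd = a(i, k) - cen[k];
      msq += dd * dd;
    }
  double scale2 = (double)(msq / M);
  double eps2 = 1e-20 * scale2;  // (1e-10 * scale)^2
  std::vector<int> nb(Mu, -1);
  for (int i = 0; i < Mu; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < Mu; ++j) {
      int lag = i - j; if (lag < 0) lag = -lag;
      if (lag <= theiler) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = a(i, k) - a(j, k);
        d += dd * dd;
      }
      if (d > eps2 && d < best) { best = d; bj = j; }
    }
    nb[i] = bj;
  }
  NumericVector curve(nsteps + 1);
  IntegerVector npairs(nsteps + 1);
  for (int k = 0; k <= nsteps; ++k) {
    long double s = 0.0;
    int c = 0;
    for (int i = 0; i < Mu; ++i) {
      int j = nb[i];
      if (j < 0) continue;
      double d = 0.0;
      for (int q = 0; q < m; ++q) {
        double dd = a(i + k, q) - a(j + k, q);
        d += dd * dd;
      }
      if (d < eps2) d = eps2;  // clamp, keeping the pair set fixed
      s += 0.5 * std::log(d);
      ++c;
    }
    curve[k] = (c > 0) ? (double)(s / c) : NA_REAL;
    npairs[k] = c;
  }
  return List::create(_["curve"] = curve, _["n_pairs"] = npairs);
}

// Kennel false-nearest-neighbour fraction going from dimension d to d+1
// (distance-ratio threshold rtol plus the attractor-size criterion atol).
// [[Rcpp::export]]
double cf_fnn_fraction(NumericVector x, int tau, int d, int theiler,
                       double rtol, double atol) {
  int N = x.size();
  int M = N - d * tau;  // points whose (d+1)-th coordinate exists
  if (M < 2) return NA_REAL;
  long double mu = 0.0, ss = 0.0;
  for (int i = 0; i < N; ++i) mu += x[i];
  mu /= N;
  for (int i = 0; i < N; ++i) { double dd = x[i] - mu; ss += dd * dd; }
  double sx = std::sqrt((double)(ss / N));
  if (sx <= 0.0) return NA_REAL;
  int nfalse = 0, nvalid = 0;
  for (int i = 0; i < M; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < M; ++j) {
      int lag = i - j; if (lag < 0) lag = -lag;
      if (lag <= theiler) continue;
      double dist = 0.0;
      for (int k = 0; k < d; ++k) {
        double dd = x[i + k * tau] - x[j + k * tau];
        dist += dd * dd;
      }
      if (dist < best) { best = dist; bj = j; }
    }
    if (bj < 0) continue;
    double Rd = std::sqrt(best);
    double extra = std::fabs(x[i + d * tau] - x[bj + d * tau]);
    ++nvalid;
    // distances at the machine-noise floor (exact revisits of a noiseless
    // orbit) carry no geometric information for the ratio criterion
    double eps = 1e-10 * sx;
    bool is_false = false;
    if (extra > eps && (Rd <= 0.0 || extra / Rd > rtol)) is_false = true;
    if (std::sqrt(Rd * Rd + extra * extra) / sx > atol) is_false = true;
    if (is_false) ++nfalse;
  }
  if (nvalid == 0) return NA_REAL;
  return (double)nfalse / (double)nvalid;
}
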