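// Z-score event-model internals: piecewise-linear trajectories, per-stage
// Gaussian log-likelihoods, and the greedy single-event relocation search.
// Events are identified 1..N; an ordering is the vector of event ids by
// stage position 1..N. Stage k means the first k events have occurred.
//
// The hot path (candidate evaluation inside the greedy search) works on a
// transposed copy of the z-matrix so that each subject's biomarker vector
// and each stage's trajectory column are contiguous in memory.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Fill T (K x (N+1), column-major) with the expected z-value of each
// biomarker at integer stages 0..N. Anchors: (0, 0), each of the
// biomarker's events at its stage position, and (N, zmax). Stage N always
// evaluates to zmax (the plateau anchor wins if an event sits at the final
// position).
static void traj_fill(const std::vector<int>& ev_bio,
                      const std::vector<double>& ev_z,
                      const std::vector<int>& ordering,
                      int K, double zmax, double* T) {
  const int N = static_cast<int>(ordering.size());
  std::vector<int> pos(N);
  for (int p = 0; p < N; ++p) pos[ordering[p] - 1] = p + 1;

  std::vector<std::vector<std::pair<int, double> > > anchors(K);
  for (int e = 0; e < N; ++e)
    anchors[ev_bio[e] - 1].push_back(std::make_pair(pos[e], ev_z[e]));

  for (int i = 0; i < K; ++i) {
    std::vector<std::pair<int, double> >& a = anchors[i];
    std::sort(a.begin(), a.end());
    std::vector<double> xs, ys;
    xs.push_back(0.0); ys.push_back(0.0);
    for (size_t j = 0; j < a.size(); ++j) {
      xs.push_back(static_cast<double>(a[j].first));
      ys.push_back(a[j].second);
    }
    if (a.empty() || a.back().first < N) {
      xs.push_back(static_cast<double>(N));
      ys.push_back(zmax);
    }
    const int nseg = static_cast<int>(xs.size()) - 1;
    int seg = 0;
    for (int k = 0; k <= N; ++k) {
      if (k == N) { T[i + static_cast<size_t>(k) * K] = zmax; continue; }
      while (seg < nseg - 1 && static_cast<double>(k) > xs[seg + 1]) ++seg;
      const double x0 = xs[seg], x1 = xs[seg + 1];
      T[i + static_cast<size_t>(k) * K] = (x1 > x0)
        ? ys[seg] + (ys[seg + 1] - ys[seg]) * (k - x0) / (x1 - x0)
        : ys[seg + 1];
    }
  }
}

static std::vector<int> as_std_int(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

// log of the stage-marginal likelihood per subject (uniform stage prior):
// log( (1/S) * sum_k exp(L_sk) ), with L the Gaussian stage log-likelihood.
// Zt is K x n (subjects contiguous), T is K x S, both column-major.
static void marginal_core(const double* Zt, int n, int K, const double* T,
                          int S, const double* inv_sd2, double cst,
                          double* out, std::vector<double>& row) {
  const double logS = std::log(static_cast<double>(S));
  for (int s = 0; s < n; ++s) {
    const double* z = Zt + static_cast<size_t>(s) * K;
    double mx = -INFINITY;
    for (int k = 0; k < S; ++k) {
      const double* t = T + static_cast<size_t>(k) * K;
      double acc = 0.0;
      for (int i = 0; i < K; ++i) {
        const double d = z[i] - t[i];
        acc += d * d * inv_sd2[i];
      }
      const double v = cst - 0.5 * acc;
      row[k] = v;
      if (v > mx) mx = v;
    }
    double sum = 0.0;
    for (int k = 0; k < S; ++k) sum += std::exp(row[k] - mx);
    out[s] = mx + std::log(sum) - logS;
  }
}

static double gauss_const(const NumericVector& sd, int K) {
  double cst = -0.5 * K * LOG2PI;
  for (int i = 0; i < K; ++i) cst -= std::log(sd[i]);
  return cst;
}

static std::vector<double> transpose_z(const NumericMatrix& Z) {
  const int n = Z.nrow(), K = Z.ncol();
  std::vector<double> Zt(static_cast<size_t>(n) * K);
  for (int s = 0; s < n; ++s)
    for (int i = 0; i < K; ++i)
      Zt[static_cast<size_t>(s) * K + i] = Z(s, i);
  return Zt;
}

static std::vector<double> inv_sd_sq(const NumericVector& sd) {
  std::vector<double> v(sd.size());
  for (int i = 0; i < sd.size(); ++i) v[i] = 1.0 / (sd[i] * sd[i]);
  return v;
}

// [[Rcpp::export]]
NumericMatrix traj_matrix_cpp(IntegerVector ev_bio, NumericVector ev_z,
                              IntegerVector ordering, int K, double zmax) {
  const int N = ordering.size();
  NumericMatrix T(K, N + 1);
  std::vector<double> z(ev_z.begin(), ev_z.end());
  std::vector<int> bio = as_std_int(ev_bio), ord = as_std_int(ordering);
  traj_fill(bio, z, ord, K, zmax, T.begin());
  return T;
}

// Per-subject, per-stage Gaussian log-likelihood given a trajectory matrix.
// [[Rcpp::export]]
NumericMatrix stage_loglik_cpp(NumericMatrix Z, NumericMatrix T,
                               NumericVector sd) {
  const int n = Z.nrow(), K = Z.ncol(), S = T.ncol();
  const double cst = gauss_const(sd, K);
  std::vector<double> Zt = transpose_z(Z);
  std::vector<double> isd2 = inv_sd_sq(sd);
  NumericMatrix L(n, S);
  const double* Tp = T.begin();
  for (int s = 0; s < n; ++s) {
    const double* z = &Zt[static_cast<size_t>(s) * K];
    for (int k = 0; k < S; ++k) {
      const double* t = Tp + static_cast<size_t>(k) * K;
      double acc = 0.0;
      for (int i = 0; i < K; ++i) {
        const double d = z[i] - t[i];
        acc += d * d * isd2[i];
      }
      L(s, k) = cst - 0.5 * acc;
    }
  }
  return L;
}

// [[Rcpp::export]]
NumericVector stage_marginal_loglik_cpp(NumericMatrix Z, IntegerVector ev_bio,
                                        NumericVector ev_z,
                                        IntegerVector ordering,
                                        NumericVector sd, double zmax) {
  const int N = ordering.size(), K = Z.ncol(), n = Z.nrow();
  std::vector<double> T(static_cast<size_t>(K) * (N + 1));
  std::vector<double> z(ev_z.begin(), ev_z.end());
  std::vector<int> bio = as_std_int(ev_bio), ord = as_std_int(ordering);
  traj_fill(bio, z, ord, K, zmax, T.data());
  std::vector<double> Zt = transpose_z(Z);
  std::vector<double> isd2 = inv_sd_sq(sd);
  std::vector<double> row(N + 1);
  NumericVector out(n);
  marginal_core(Zt.data(), n, K, T.data(), N + 1, isd2.data(),
                gauss_const(sd, K), out.begin(), row);
  return out;
}

// Greedy maximum-likelihood ordering search by iterated single-event
// relocation: each event in turn is moved to the position that maximizes
// the (weight-summed) stage-marginal log-likelihood; sweeps repeat until no
// relocation improves the objective. Ties resolve to the lowest position.
// [[Rcpp::export]]
List greedy_fit_cpp(NumericMatrix Z, IntegerVector ev_bio, NumericVector ev_z,
                    IntegerVector init_ordering, NumericVector sd,
                    double zmax, NumericVector w, int max_sweeps = 100) {
  const int N = init_ordering.size(), K = Z.ncol(), n = Z.nrow();
  std::vector<double> z(ev_z.begin(), ev_z.end());
  std::vector<int> bio = as_std_int(ev_bio);
  std::vector<int> ord = as_std_int(init_ordering);
  std::vector<double> T(static_cast<size_t>(K) * (N + 1));
  std::vector<double> Zt = transpose_z(Z);
  std::vector<double> isd2 = inv_sd_sq(sd);
  const double cst = gauss_const(sd, K);
  std::vector<double> marg(n), row(N + 1);

  double wtot; // objective = sum_s w_s * marginal_s
  const double eps = 1e-9;
  double best;
  {
    traj_fill(bio, z, ord, K, zmax, T.data());
    marginal_core(Zt.data(), n, K, T.data(), N + 1, isd2.data(), cst,
                  marg.data(), row);
    wtot = 0.0;
    for (int s = 0; s < n; ++s) wtot += w[s] * marg[s];
    best = wtot;
  }

  int sweeps = 0;
  bool improved = true;
  std::vector<int> cand(N);
  while (improved && sweeps < max_sweeps) {
    improved = false;
    ++sweeps;
    for (int e = 1; e <= N; ++e) {
      int p = 0;
      for (int j = 0; j < N; ++j) if (ord[j] == e) { p = j; break; }
      double bestval = best;
      int bestq = p;
      for (int q = 0; q < N; ++q) {
        if (q == p) continue;
        cand = ord;
        cand.erase(cand.begin() + p);
        cand.insert(cand.begin() + q, e);
        traj_fill(bio, z, cand, K, zmax, T.data());
        marginal_core(Zt.data(), n, K, T.data(), N + 1, isd2.data(), cst,
                      marg.data(), row);
        double v = 0.0;
        for (int s = 0; s < n; ++s) v += w[s] * marg[s];
        if (v > bestval + eps) { bestval = v; bestq = q; }
      }
      if (bestq != p) {
        ord.erase(ord.begin() + p);
        ord.insert(ord.begin() + bestq, e);
        best = bestval;
        improved = true;
      }
    }
  }
  return List::create(_["ordering"] = IntegerVector(ord.begin(), ord.end()),
                      _["loglik"] = best,
                      _["sweeps"] = sweeps);
}
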