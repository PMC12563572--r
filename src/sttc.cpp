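#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fraction of [0, duration] tiled by the union of [t - dt, t + dt] windows
// around the (sorted) spikes, clipped to the recording and with overlaps
// merged exactly.
static double tiled_fraction(const double* t, int n, double duration, double dt) {
  if (n == 0) return 0.0;
  double total = 0.0;
  double lo = t[0] - dt, hi = t[0] + dt;
  for (int k = 1; k < n; ++k) {
    double a = t[k] - dt, b = t[k] + dt;
    if (a <= hi) {
      if (b > hi) hi = b;
    } else {
      total += std::min(hi, duration) - std::max(lo, 0.0);
      lo = a; hi = b;
    }
  }
  total += std::min(hi, duration) - std::max(lo, 0.0);
  return total / duration;
}

// Fraction of spikes in `a` lying within +/- dt of any spike in `b`.
// Two-pointer sweep over sorted trains.
static double prop_within(const double* a, int na, const double* b, int nb,
                          double dt) {
  int hits = 0, j = 0;
  for (int i = 0; i < na; ++i) {
    while (j < nb && b[j] < a[i] - dt) ++j;
    if (j < nb && b[j] <= a[i] + dt) ++hits;
  }
  return (double)hits / (double)na;
}

static double sttc_core(const double* a, int na, const double* b, int nb,
                        double duration, double dt) {
  double ta = tiled_fraction(a, na, duration, dt);
  double tb = tiled_fraction(b, nb, duration, dt);
  double pa = prop_within(a, na, b, nb, dt);
  double pb = prop_within(b, nb, a, na, dt);
  double den1 = 1.0 - pa * tb, den2 = 1.0 - pb * ta;
  if (den1 == 0.0 || den2 == 0.0)
    stop("STTC undefined: denominator 1 - P*T is zero (P_A=%g T_B=%g P_B=%g T_A=%g)",
         pa, tb, pb, ta);
  return 0.5 * ((pa - tb) / den1 + (pb - ta) / den2);
}

// [[Rcpp::export]]
double sttc_cpp(NumericVector a, NumericVector b, double duration, double dt) {
  if (a.size() == 0 || b.size() == 0)
    stop("STTC requires non-empty spike trains");
  return sttc_core(a.begin(), a.size(), b.begin(), b.size(), duration, dt);
}

// Jittered surrogate of one train: Gaussian displacement, re-sorted, clipped.
// Consumes the R RNG stream so seeding is done with set.seed() in R.
static std::vector<double> jitter_sorted(const std::vector<double>& t,
                                         double sd, double duration) {
  std::vector<double> out(t.size());
  for (size_t k = 0; k < t.size(); ++k) {
    double x = t[k] + norm_rand() * sd;
    if (x < 0) x = 0;
    if (x > duration) x = duration;
    out[k] = x;
  }
  std::sort(out.begin(), out.end());
  return out;
}

// Pairwise STTC matrix plus one-sided surrogate p-values.
// For each unit a bank of n_surr jittered surrogates is generated (in unit
// order, from the current R RNG state); surrogate STTC for pair (i, j) at
// permutation s pairs surrogate s of unit i with surrogate s of unit j.
// p = (1 + #{surrogate >= empirical}) / (n_surr + 1).
// [[Rcpp::export]]
List sttc_pvalue_matrix_cpp(List trains, double duration, double dt,
                            int n_surr, double jitter_sd) {
  int n = trains.size();
  std::vector<std::vector<double> > tr(n);
  for (int i = 0; i < n; ++i) {
    NumericVector v = trains[i];
    tr[i] = std::vector<double>(v.begin(), v.end());
    if (tr[i].empty()) stop("unit %d has an empty spike train", i + 1);
  }

  // surrogate banks: banks[i][s] is surrogate s of unit i
  std::vector<std::vector<std::vector<double> > > banks(n);
  for (int i = 0; i < n; ++i) {
    banks[i].reserve(n_surr);
    for (int s = 0; s < n_surr; ++s)
      banks[i].push_back(jitter_sorted(tr[i], jitter_sd, duration));
  }

  NumericMatrix W(n, n), P(n, n);
  W.fill(0.0); P.fill(1.0);
  for (int i = 0; i < n; ++i) W(i, i) = 1.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double emp = sttc_core(tr[i].data(), tr[i].size(),
                             tr[j].data(), tr[j].size(), duration, dt);
      int ge = 0;
      for (int s = 0; s < n_surr; ++s) {
        double sv = sttc_core(banks[i][s].data(), banks[i][s].size(),
                              banks[j][s].data(), banks[j][s].size(),
                              duration, dt);
        if (sv >= emp) ++ge;
      }
      double p = (1.0 + ge) / (double)(n_surr + 1);
      W(i, j) = W(j, i) = emp;
      P(i, j) = P(j, i) = p;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["sttc"] = W, _["p"] = P);
}
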