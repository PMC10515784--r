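#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis core for the EPBD lattice. Uses R's RNG (unif_rand / norm_rand)
// so that, for a given set.seed(), the stream is identical to the pure-R
// reference engine: per attempt the draws are
//   site uniform, [strand uniform if per_strand], normal increment,
//   [acceptance uniform only when dE > 0 and the candidate is in bounds].

static inline double morse(double y, double D, double a) {
  double e = std::expm1(-a * y);
  return D * e * e;
}

static inline double stack(double y, double yp, double k, double rho, double b) {
  double d = y - yp;
  return 0.5 * k * (1.0 + rho * std::exp(-b * (y + yp))) * d * d;
}

// [[Rcpp::export]]
List epbd_mcmc_cpp(NumericVector D, NumericVector a, NumericVector kstep,
                   double rho, double b, double beta,
                   double ymin, double ymax,
                   NumericVector y_init, NumericVector sigma,
                   double preheat_steps, double measure_steps,
                   int record_interval, int attempts_per_step,
                   bool per_strand) {
  const int N = D.size();
  std::vector<double> y(y_init.begin(), y_init.end());

  double E = 0.0;
  for (int i = 0; i < N; ++i) E += morse(y[i], D[i], a[i]);
  for (int i = 1; i < N; ++i) E += stack(y[i], y[i - 1], kstep[i - 1], rho, b);

  long long accepted = 0, proposed = 0;
  const long long S = (long long)(measure_steps) / record_interval;
  NumericMatrix snaps(S, N);
  long long snap_i = 0;

  auto attempt = [&]() {
    double u1 = unif_rand();
    int site = (int)(N * u1);
    if (site >= N) site = N - 1;
    double delta;
    if (per_strand) {
      double u2 = unif_rand();
      double sgn = (u2 < 0.5) ? 1.0 : -1.0;
      delta = sgn * norm_rand() * sigma[site] / std::sqrt(2.0);
    } else {
      delta = norm_rand() * sigma[site];
    }
    ++proposed;
    double yo = y[site], yn = yo + delta;
    if (yn < ymin || yn > ymax) return;  // out-of-bounds moves are rejected
    double dE = morse(yn, D[site], a[site]) - morse(yo, D[site], a[site]);
    if (site > 0)
      dE += stack(yn, y[site - 1], kstep[site - 1], rho, b)
          - stack(yo, y[site - 1], kstep[site - 1], rho, b);
    if (site < N - 1)
      dE += stack(y[site + 1], yn, kstep[site], rho, b)
          - stack(y[site + 1], yo, kstep[site], rho, b);
    bool acc;
    if (dE <= 0.0) acc = true;
    else acc = (unif_rand() < std::exp(-dE * beta));
    if (acc) {
      y[site] = yn;
      E += dE;
      ++accepted;
    }
  };

  const long long pre = (long long)preheat_steps;
  const long long mea = (long long)measure_steps;
  for (long long t = 0; t < pre; ++t)
    for (int j = 0; j < attempts_per_step; ++j) attempt();
  for (long long t = 1; t <= mea; ++t) {
    for (int j = 0; j < attempts_per_step; ++j) attempt();
    if (t % record_interval == 0 && snap_i < S) {
      for (int i = 0; i < N; ++i) snaps(snap_i, i) = y[i];
      ++snap_i;
    }
  }

  return List::create(_["snapshots"] = snaps,
                      _["final_y"] = NumericVector(y.begin(), y.end()),
                      _["energy"] = E,
                      _["accepted"] = (double)accepted,
                      _["proposed"] = (double)proposed);
}
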