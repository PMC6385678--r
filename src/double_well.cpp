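// 1-D double-well Langevin fixture: U(x) = h (x^2 - 1)^2, overdamped
// Euler-Maruyama with diffusion coefficient D.  Used for the unbiasedness
// check of the WE resampler against a long brute-force trajectory.

#include <Rcpp.h>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_dw_propagate(NumericVector x, int n_steps, double h,
                               double D, double dt, double kT, double seed,
                               IntegerVector ids, int iteration) {
  int n = x.size();
  NumericVector out(n);
  double sdt = std::sqrt(2.0 * D * dt);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    WepRng rng(seed, ids[i], iteration);
    for (int s = 0; s < n_steps; ++s) {
      double force = -4.0 * h * xi * (xi * xi - 1.0);
      xi += (D / kT) * force * dt + sdt * rng.norm();
    }
    out[i] = xi;
  }
  return out;
}

// long unbiased trajectory, positions recorded every record_every steps
// [[Rcpp::export]]
NumericVector cpp_dw_traj(double x0, double n_steps, double h, double D,
                          double dt, double kT, double seed, int record_every) {
  WepRng rng(seed, 1, 1);
  double sdt = std::sqrt(2.0 * D * dt);
  int n_out = (int)(n_steps / record_every);
  NumericVector out(n_out);
  double xi = x0;
  for (int i = 0; i < n_out; ++i) {
    for (int s = 0; s < record_every; ++s) {
      double force = -4.0 * h * xi * (xi * xi - 1.0);
      xi += (D / kT) * force * dt + sdt * rng.norm();
    }
    out[i] = xi;
  }
  return out;
}
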