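#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double t) { return 1.0 / (1.0 + std::exp(-t)); }

// shape: 0 = plateau (difference of logistic steps at 0 and h), 1 = gaussian
static inline double force_at(double x, int shape, double U, double h, double w) {
  if (shape == 0) {
    double s0 = sigmoid(x / w), s1 = sigmoid((x - h) / w);
    return -U / w * (s0 * (1.0 - s0) - s1 * (1.0 - s1));
  }
  double d = x - 0.5 * h;
  return U * d / (w * w) * std::exp(-d * d / (2.0 * w * w));
}

// Euler-Maruyama advance of N independent overdamped particles in the
// membrane potential, reflecting outer walls.  Uses R's RNG so runs are
// bit-reproducible under set.seed().  Accumulates, after n_equil steps,
// per-block means of the summed membrane force on the particles and
// per-block position histograms on uniform bins.
// [[Rcpp::export]]
List brownian_core(NumericVector x0, double mu, double Ds, double dt,
                   int n_equil, int n_steps, int n_blocks,
                   double xmin, double xmax,
                   int shape, double U_max, double h, double w,
                   double bin_lo, double bin_hi, int n_bins) {
  const int N = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  const double sigma = std::sqrt(2.0 * Ds * dt);
  const double inv_bw = n_bins / (bin_hi - bin_lo);

  const int block_len = n_steps / n_blocks;
  const int n_used = block_len * n_blocks;

  NumericVector block_force(n_blocks);        // mean over block of sum_i F_i
  NumericMatrix hist(n_blocks, n_bins);       // occupancy counts per block

  // equilibration
  for (int s = 0; s < n_equil; ++s) {
    for (int i = 0; i < N; ++i) {
      double xi = x[i];
      xi += mu * force_at(xi, shape, U_max, h, w) * dt + sigma * norm_rand();
      while (xi < xmin || xi > xmax) {
        if (xi < xmin) xi = 2.0 * xmin - xi; else xi = 2.0 * xmax - xi;
      }
      x[i] = xi;
    }
  }

  for (int s = 0; s < n_used; ++s) {
    const int b = s / block_len;
    double fsum = 0.0;
    for (int i = 0; i < N; ++i) {
      double xi = x[i];
      const double f = force_at(xi, shape, U_max, h, w);
      fsum += f;
      xi += mu * f * dt + sigma * norm_rand();
      while (xi < xmin || xi > xmax) {
        if (xi < xmin) xi = 2.0 * xmin - xi; else xi = 2.0 * xmax - xi;
      }
      x[i] = xi;
      int bin = (int)std::floor((xi - bin_lo) * inv_bw);
      if (bin < 0) bin = 0;
      if (bin >= n_bins) bin = n_bins - 1;
      hist(b, bin) += 1.0;
    }
    block_force[b] += fsum / block_len;
  }

  return List::create(_["block_force"] = block_force,
                      _["hist"] = hist,
                      _["final_x"] = NumericVector(x.begin(), x.end()),
                      _["n_steps_used"] = n_used);
}
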