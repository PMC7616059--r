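#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin annealing of a particle-on-a-string polymer under
// flat-bottom harmonic distance restraints and soft quadratic excluded
// volume.  Distances are in bead-radius units.  Randomness comes from
// R's RNG, so results are reproducible under set.seed().
//
// coords: n x 3 starting coordinates (modified copy returned)
// ri, rj: 0-based restraint bead indices
// lower, upper: flat-bottom bounds per restraint (radii)
// temps: temperature per annealing stage (decreasing)
// steps_per_temp: Langevin steps per stage
// dt: integration step
// rep_dist: excluded-volume onset distance (radii)
// rep_k, res_k: force constants for repulsion and restraints
// max_step: per-step displacement cap (radii)

static inline double sq(double x) { return x * x; }

// [[Rcpp::export]]
NumericMatrix anneal_core(NumericMatrix coords_in, IntegerVector ri,
                          IntegerVector rj, NumericVector lower,
                          NumericVector upper, NumericVector temps,
                          int steps_per_temp, double dt, double rep_dist,
                          double rep_k, double res_k, double max_step) {
  const int n = coords_in.nrow();
  const int nr = ri.size();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords_in(i, 0); y[i] = coords_in(i, 1); z[i] = coords_in(i, 2);
  }
  std::vector<double> fx(n), fy(n), fz(n);
  const double cell = rep_dist;
  std::vector<int> head, nxt(n);

  for (int stage = 0; stage < temps.size(); ++stage) {
    const double T = temps[stage];
    const double noise = std::sqrt(2.0 * T * dt);
    for (int step = 0; step < steps_per_temp; ++step) {
      std::fill(fx.begin(), fx.end(), 0.0);
      std::fill(fy.begin(), fy.end(), 0.0);
      std::fill(fz.begin(), fz.end(), 0.0);

      // restraint forces (flat-bottom harmonic)
      for (int r = 0; r < nr; ++r) {
        const int a = ri[r], b = rj[r];
        double dx = x[b] - x[a], dy = y[b] - y[a], dz = z[b] - z[a];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < 1e-9) { dx = 1e-4; dy = 0; dz = 0; d = 1e-4; }
        // force is linear within half a radius of the bounds and
        // constant beyond (robust to irreconcilable noise restraints)
        double f = 0.0;
        if (d < lower[r]) f = res_k * std::min(lower[r] - d, 0.5);
        else if (d > upper[r]) f = -res_k * std::min(d - upper[r], 0.5);
        if (f != 0.0) {
          const double s = f / d;
          fx[a] -= s * dx; fy[a] -= s * dy; fz[a] -= s * dz;
          fx[b] += s * dx; fy[b] += s * dy; fz[b] += s * dz;
        }
      }

      // excluded volume via a uniform spatial grid of cell size rep_dist
      double mnx = x[0], mny = y[0], mnz = z[0], mxx = x[0], mxy = y[0], mxz = z[0];
      for (int i = 1; i < n; ++i) {
        mnx = std::min(mnx, x[i]); mxx = std::max(mxx, x[i]);
        mny = std::min(mny, y[i]); mxy = std::max(mxy, y[i]);
        mnz = std::min(mnz, z[i]); mxz = std::max(mxz, z[i]);
      }
      const int gx = std::max(1, (int)((mxx - mnx) / cell) + 1);
      const int gy = std::max(1, (int)((mxy - mny) / cell) + 1);
      const int gz = std::max(1, (int)((mxz - mnz) / cell) + 1);
      head.assign((size_t)gx * gy * gz, -1);
      std::vector<int> ci(n), cj(n), ck(n);
      for (int i = 0; i < n; ++i) {
        ci[i] = std::min(gx - 1, (int)((x[i] - mnx) / cell));
        cj[i] = std::min(gy - 1, (int)((y[i] - mny) / cell));
        ck[i] = std::min(gz - 1, (int)((z[i] - mnz) / cell));
        const size_t c = ((size_t)ci[i] * gy + cj[i]) * gz + ck[i];
        nxt[i] = head[c]; head[c] = i;
      }
      for (int i = 0; i < n; ++i) {
        for (int a = std::max(0, ci[i] - 1); a <= std::min(gx - 1, ci[i] + 1); ++a)
          for (int b = std::max(0, cj[i] - 1); b <= std::min(gy - 1, cj[i] + 1); ++b)
            for (int c = std::max(0, ck[i] - 1); c <= std::min(gz - 1, ck[i] + 1); ++c) {
              int j = head[((size_t)a * gy + b) * gz + c];
              while (j >= 0) {
                if (j > i) {
                  double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
                  double d2 = dx * dx + dy * dy + dz * dz;
                  if (d2 < sq(rep_dist) && d2 > 1e-18) {
                    double d = std::sqrt(d2);
                    double s = rep_k * (rep_dist - d) / d;  // push apart
                    fx[i] -= s * dx; fy[i] -= s * dy; fz[i] -= s * dz;
                    fx[j] += s * dx; fy[j] += s * dy; fz[j] += s * dz;
                  }
                }
                j = nxt[j];
              }
            }
      }

      // Langevin update with displacement cap
      for (int i = 0; i < n; ++i) {
        double ddx = fx[i] * dt + noise * norm_rand();
        double ddy = fy[i] * dt + noise * norm_rand();
        double ddz = fz[i] * dt + noise * norm_rand();
        const double mag = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
        if (mag > max_step) {
          const double sc = max_step / mag;
          ddx *= sc; ddy *= sc; ddz *= sc;
        }
        x[i] += ddx; y[i] += ddy; z[i] += ddz;
      }
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return out;
}

// Total potential energy (restraints + excluded volume); used for the
// energy-decrease invariant and audit reports.
// [[Rcpp::export]]
double polymer_energy(NumericMatrix coords, IntegerVector ri, IntegerVector rj,
                      NumericVector lower, NumericVector upper,
                      double rep_dist, double rep_k, double res_k) {
  const int n = coords.nrow();
  double e = 0.0;
  for (int r = 0; r < ri.size(); ++r) {
    const int a = ri[r], b = rj[r];
    const double d = std::sqrt(sq(coords(b,0) - coords(a,0)) +
                               sq(coords(b,1) - coords(a,1)) +
                               sq(coords(b,2) - coords(a,2)));
    if (d < lower[r]) e += 0.5 * res_k * sq(lower[r] - d);
    else if (d > upper[r]) e += 0.5 * res_k * sq(d - upper[r]);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double d2 = sq(coords(j,0) - coords(i,0)) +
                        sq(coords(j,1) - coords(i,1)) +
                        sq(coords(j,2) - coords(i,2));
      if (d2 < sq(rep_dist)) e += 0.5 * rep_k * sq(rep_dist - std::sqrt(d2));
    }
  return e;
}

// Marginal Poisson-beta log-likelihood over a Beta quantile grid:
// sum_u mult[u] * log( mean_k Poisson(uniq[u]; s * pgrid[k]) ).
// [[Rcpp::export]]
double pb_loglik(IntegerVector uniq, NumericVector mult, NumericVector pgrid,
                 double s) {
  const int K = pgrid.size(), U = uniq.size();
  std::vector<double> lam(K), llam(K);
  for (int k = 0; k < K; ++k) {
    lam[k] = std::max(s * pgrid[k], 1e-300);
    llam[k] = std::log(lam[k]);
  }
  double total = 0.0;
  for (int u = 0; u < U; ++u) {
    const double c = uniq[u];
    const double lg = R::lgammafn(c + 1.0);
    // stabilise the average with the max exponent
    double mx = -INFINITY;
    for (int k = 0; k < K; ++k) {
      const double e = c * llam[k] - lam[k] - lg;
      if (e > mx) mx = e;
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(c * llam[k] - lam[k] - lg - mx);
    total += mult[u] * (mx + std::log(acc / K));
  }
  return total;
}
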