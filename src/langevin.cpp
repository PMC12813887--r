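#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) integrator for the bead-spring
// receptor model:
//   x <- x + (dt/gamma) * F(x) + sqrt(2 kT dt / gamma) * eta
// Forces: harmonic bonds, discrete-curvature bending (harmonic in the
// second difference of positions), harmonic anchors to fixed sites, and
// half-harmonic slab walls in z. Uses R's RNG (norm_rand) so seeding via
// set.seed() in R gives run-to-run reproducibility.
//
// bonds:   n_b x 4  (i, j, k, r0)         1-based indices
// angles:  n_a x 4  (i, j, k, k_angle)
// anchors: n_c x 5  (i, sx, sy, sz, k)
// walls:   n_w x 4  (i, side, z0, k)      side +1: keep z >= z0; -1: z <= z0
//
// Frames are recorded every `stride` steps (steps stride, 2*stride, ...).
// Returns an n_saved x (3 n_beads) matrix (x1 y1 z1 x2 ...).

// [[Rcpp::export]]
NumericMatrix simulate_langevin_cpp(NumericMatrix x0,
                                    NumericMatrix bonds,
                                    NumericMatrix angles,
                                    NumericMatrix anchors,
                                    NumericMatrix walls,
                                    double dt, double gamma_, double kT,
                                    int n_steps, int stride) {
  const int n = x0.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = x0(i, d);

  const int n_saved = n_steps / stride;
  NumericMatrix out(n_saved, 3 * n);
  const double mob = dt / gamma_;
  const double noise = std::sqrt(2.0 * kT * dt / gamma_);
  const double max_move = 10.0;  // instability guard, Angstrom per step

  GetRNGstate();
  int saved = 0;
  for (int step = 1; step <= n_steps; ++step) {
    std::fill(f.begin(), f.end(), 0.0);

    for (int b = 0; b < bonds.nrow(); ++b) {
      const int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
      const double kb = bonds(b, 2), r0 = bonds(b, 3);
      double d[3], r2 = 0.0;
      for (int c = 0; c < 3; ++c) { d[c] = x[3*j+c] - x[3*i+c]; r2 += d[c]*d[c]; }
      const double r = std::sqrt(r2);
      if (r > 1e-12) {
        const double fac = kb * (r - r0) / r;
        for (int c = 0; c < 3; ++c) { f[3*i+c] += fac * d[c]; f[3*j+c] -= fac * d[c]; }
      }
    }

    for (int a = 0; a < angles.nrow(); ++a) {
      const int i = (int)angles(a, 0) - 1, j = (int)angles(a, 1) - 1,
                k = (int)angles(a, 2) - 1;
      const double ka = angles(a, 3);
      for (int c = 0; c < 3; ++c) {
        const double d2 = x[3*i+c] - 2.0 * x[3*j+c] + x[3*k+c];
        f[3*i+c] -= ka * d2;
        f[3*j+c] += 2.0 * ka * d2;
        f[3*k+c] -= ka * d2;
      }
    }

    for (int a = 0; a < anchors.nrow(); ++a) {
      const int i = (int)anchors(a, 0) - 1;
      const double ka = anchors(a, 4);
      for (int c = 0; c < 3; ++c)
        f[3*i+c] -= ka * (x[3*i+c] - anchors(a, 1 + c));
    }

    for (int w = 0; w < walls.nrow(); ++w) {
      const int i = (int)walls(w, 0) - 1;
      const double side = walls(w, 1), z0 = walls(w, 2), kw = walls(w, 3);
      const double viol = side * (z0 - x[3*i+2]);
      if (viol > 0.0) f[3*i+2] += side * kw * viol;
    }

    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) {
        const double drift = mob * f[3*i+c];
        if (std::fabs(drift) > max_move) {
          PutRNGstate();
          stop("Langevin instability at step %d: |F| dt/gamma = %.2f A on bead %d",
               step, std::fabs(drift), i + 1);
        }
        x[3*i+c] += drift + noise * norm_rand();
      }

    if (step % stride == 0) {
      for (int i = 0; i < 3 * n; ++i) out(saved, i) = x[i];
      ++saved;
    }
  }
  PutRNGstate();
  return out;
}
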