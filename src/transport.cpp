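// Voxel Monte-Carlo photon transport in a homogeneous scattering medium.
//
// Hop-drop-spin with absorption weighting: at each interaction the photon
// deposits w * mu_a/mu_t into the enclosing voxel and continues with the
// scattered remainder; low-weight photons are terminated unbiasedly by
// Russian roulette.  The RNG is xoshiro256** seeded via splitmix64 from a
// user-supplied integer, so runs are reproducible independently of R's RNG.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1]
  inline double unif_oc() { return 1.0 - unif(); }
};

struct Kahan {
  double sum = 0.0, c = 0.0;
  inline void add(double x) {
    double y = x - c;
    double t = sum + y;
    c = (t - sum) - y;
    sum = t;
  }
};

inline double hg_cosine(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// rotate direction d by polar angle (ct, st) and azimuth psi
inline void spin(double ct, double st, double psi, double& ux, double& uy,
                 double& uz) {
  double cp = std::cos(psi), sp = std::sin(psi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -den * st * cp + uz * ct;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm;
    uy = ny / norm;
    uz = nz / norm;
  }
}

// orthonormal basis (e1, e2) perpendicular to unit vector n
inline void basis(const double n[3], double e1[3], double e2[3]) {
  if (std::fabs(n[0]) < 0.9) {
    e1[0] = 0.0; e1[1] = -n[2]; e1[2] = n[1];
  } else {
    e1[0] = -n[2]; e1[1] = 0.0; e1[2] = n[0];
  }
  double l = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  e1[0] /= l; e1[1] /= l; e1[2] /= l;
  e2[0] = n[1] * e1[2] - n[2] * e1[1];
  e2[1] = n[2] * e1[0] - n[0] * e1[2];
  e2[2] = n[0] * e1[1] - n[1] * e1[0];
}

struct Grid {
  int nx, ny, nz;
  double h, ox, oy, oz;
  inline long index(double x, double y, double z) const {
    double fx = (x - ox) / h, fy = (y - oy) / h, fz = (z - oz) / h;
    if (fx < 0.0 || fy < 0.0 || fz < 0.0) return -1;
    int ix = static_cast<int>(fx), iy = static_cast<int>(fy),
        iz = static_cast<int>(fz);
    if (ix >= nx || iy >= ny || iz >= nz) return -1;
    return static_cast<long>(ix) +
           static_cast<long>(nx) * (static_cast<long>(iy) +
                                    static_cast<long>(ny) * iz);
  }
};

struct Totals {
  Kahan deposited, escaped, rr_loss, rr_gain;
  double max_balance_err = 0.0;
};

// Trace one photon from (pos, dir, w); deposits into dep.
inline void trace(double px, double py, double pz, double ux, double uy,
                  double uz, double w, const Grid& grid, double mu_a,
                  double mu_s, double g, double rr_threshold,
                  double rr_survival, long max_steps, Xoshiro256& rng,
                  double* dep, Totals& tot) {
  const double mu_t = mu_a + mu_s;
  const double albedo_dep = mu_a / mu_t;
  const double launched = w;
  double dep_i = 0.0, esc_i = 0.0, loss_i = 0.0, gain_i = 0.0;

  for (long step = 0; step < max_steps; ++step) {
    double s = -std::log(rng.unif_oc()) / mu_t;
    px += s * ux; py += s * uy; pz += s * uz;
    long idx = grid.index(px, py, pz);
    if (idx < 0) { esc_i = w; w = 0.0; break; }
    double d = w * albedo_dep;
    dep[idx] += d;
    dep_i += d;
    w -= d;
    if (w <= 0.0) break;
    if (w < rr_threshold) {
      if (rng.unif() < rr_survival) {
        double w_new = w / rr_survival;
        gain_i += w_new - w;
        w = w_new;
      } else {
        loss_i = w;
        w = 0.0;
        break;
      }
    }
    double ct = hg_cosine(g, rng.unif());
    double st = std::sqrt(1.0 - ct * ct);
    spin(ct, st, 2.0 * M_PI * rng.unif(), ux, uy, uz);
  }
  // any residual (max_steps exhausted) counts as loss
  loss_i += w;

  double err = std::fabs(launched + gain_i - dep_i - esc_i - loss_i);
  if (err > tot.max_balance_err) tot.max_balance_err = err;
  tot.deposited.add(dep_i);
  tot.escaped.add(esc_i);
  tot.rr_loss.add(loss_i);
  tot.rr_gain.add(gain_i);
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_mc(IntegerVector shape, double voxel_size, NumericVector origin,
                double mu_a, double mu_s, double g, NumericVector src_center,
                NumericVector src_normal, double src_radius,
                double src_half_angle, bool isotropic, double n_photons,
                double seed, double rr_threshold, double rr_survival,
                double max_steps) {
  Grid grid{shape[0], shape[1], shape[2], voxel_size,
            origin[0], origin[1], origin[2]};
  long nvox = static_cast<long>(grid.nx) * grid.ny * grid.nz;
  NumericVector dep(nvox);
  double* depp = REAL(dep);

  double n[3] = {src_normal[0], src_normal[1], src_normal[2]};
  double e1[3], e2[3];
  basis(n, e1, e2);
  const double cos_half = std::cos(src_half_angle);

  Xoshiro256 rng(static_cast<uint64_t>(seed));
  Totals tot;
  const long np = static_cast<long>(n_photons);
  const long ms = static_cast<long>(max_steps);

  for (long i = 0; i < np; ++i) {
    // launch: uniform over the emission disc
    double r = src_radius * std::sqrt(rng.unif());
    double th = 2.0 * M_PI * rng.unif();
    double cx = r * std::cos(th), cy = r * std::sin(th);
    double px = src_center[0] + cx * e1[0] + cy * e2[0];
    double py = src_center[1] + cx * e1[1] + cy * e2[1];
    double pz = src_center[2] + cx * e1[2] + cy * e2[2];

    double ux, uy, uz;
    if (isotropic) {
      double cu = 2.0 * rng.unif() - 1.0;
      double su = std::sqrt(1.0 - cu * cu);
      double ph = 2.0 * M_PI * rng.unif();
      ux = su * std::cos(ph); uy = su * std::sin(ph); uz = cu;
    } else {
      // uniform in solid angle within the cone about the normal
      double ca = 1.0 - rng.unif() * (1.0 - cos_half);
      double sa = std::sqrt(1.0 - ca * ca);
      double ph = 2.0 * M_PI * rng.unif();
      double ax = sa * std::cos(ph), ay = sa * std::sin(ph);
      ux = ax * e1[0] + ay * e2[0] + ca * n[0];
      uy = ax * e1[1] + ay * e2[1] + ca * n[1];
      uz = ax * e1[2] + ay * e2[2] + ca * n[2];
    }

    trace(px, py, pz, ux, uy, uz, 1.0, grid, mu_a, mu_s, g, rr_threshold,
          rr_survival, ms, rng, depp, tot);
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["deposit"] = dep, _["deposited"] = tot.deposited.sum,
      _["escaped"] = tot.escaped.sum, _["rr_loss"] = tot.rr_loss.sum,
      _["rr_gain"] = tot.rr_gain.sum,
      _["max_balance_err"] = tot.max_balance_err);
}

// [[Rcpp::export]]
List cpp_propagate(NumericVector position, NumericVector direction,
                   double weight, IntegerVector shape, double voxel_size,
                   NumericVector origin, double mu_a, double mu_s, double g,
                   double seed, double rr_threshold, double rr_survival,
                   double max_steps) {
  Grid grid{shape[0], shape[1], shape[2], voxel_size,
            origin[0], origin[1], origin[2]};
  long nvox = static_cast<long>(grid.nx) * grid.ny * grid.nz;
  NumericVector dep(nvox);
  Xoshiro256 rng(static_cast<uint64_t>(seed));
  Totals tot;
  trace(position[0], position[1], position[2], direction[0], direction[1],
        direction[2], weight, grid, mu_a, mu_s, g, rr_threshold, rr_survival,
        static_cast<long>(max_steps), rng, REAL(dep), tot);
  return List::create(
      _["deposit"] = dep, _["deposited"] = tot.deposited.sum,
      _["escaped"] = tot.escaped.sum, _["rr_loss"] = tot.rr_loss.sum,
      _["rr_gain"] = tot.rr_gain.sum,
      _["balance_err"] = tot.max_balance_err);
}
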