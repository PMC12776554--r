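#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Small PRNG: one independent stream per particle, derived from the master
// seed by a fixed offset, so trajectories are reproducible irrespective of
// particle ordering. splitmix64 seeds xorshift128+; normals by Box-Muller.
namespace {

struct Stream {
  uint64_t s0, s1;
  bool has_spare;
  double spare;
};

inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline void stream_init(Stream &st, uint64_t master, uint64_t idx) {
  uint64_t x = master ^ (0xABCD1234ULL + idx * 0x9E3779B97F4A7C15ULL);
  st.s0 = splitmix64(x);
  st.s1 = splitmix64(x);
  st.has_spare = false;
  st.spare = 0.0;
}

inline uint64_t next_u64(Stream &st) {
  uint64_t x = st.s0, y = st.s1;
  st.s0 = y;
  x ^= x << 23;
  st.s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
  return st.s1 + y;
}

inline double unif01(Stream &st) {
  return (next_u64(st) >> 11) * (1.0 / 9007199254740992.0);
}

inline double norm1(Stream &st) {
  if (st.has_spare) { st.has_spare = false; return st.spare; }
  double u1 = 0.0, u2;
  while (u1 <= 0.0) u1 = unif01(st);
  u2 = unif01(st);
  double r = std::sqrt(-2.0 * std::log(u1));
  double a = 2.0 * M_PI * u2;
  st.spare = r * std::sin(a);
  st.has_spare = true;
  return r * std::cos(a);
}

// linear interpolation on a uniform grid
inline double interp(const std::vector<double> &grid_y, double lo, double h,
                     double x) {
  const int n = (int)grid_y.size();
  double t = (x - lo) / h;
  if (t <= 0.0) return grid_y[0];
  if (t >= n - 1) return grid_y[n - 1];
  int i = (int)t;
  double f = t - i;
  return grid_y[i] * (1.0 - f) + grid_y[i + 1] * f;
}

inline double wrap(double z, double half, double L, double &off) {
  while (z > half)  { z -= L; off += L; }
  while (z < -half) { z += L; off -= L; }
  return z;
}

} // namespace

// Overdamped Langevin dynamics of ions and tracer waters in a cylinder
// with periodic z. Ions feel the tabulated landscape force (kT/A) plus the
// linear voltage ramp across [s_lo, s_hi]; waters are force-free tracers.
// The driven z axis uses the Leimkuhler-Matthews update (average of
// successive Gaussians), which has high configurational accuracy at finite
// step size; x/y are plain Euler-Maruyama with wall reflection. Ion-ion
// hard-sphere overlap is handled by move rejection.
// [[Rcpp::export]]
List bd_simulate_cpp(NumericVector grid_force, double grid_lo, double grid_h,
                     double s_lo, double s_hi, double u_volt, double z_chg,
                     int n_ions, int n_waters, double D, double dt,
                     int n_steps, int stride, double pore_radius,
                     double box_height, double exclusion_radius,
                     double seed) {
  const std::vector<double> gF(grid_force.begin(), grid_force.end());
  const int np = n_ions + n_waters;
  const double sig = std::sqrt(2.0 * D * dt);
  const double half = box_height / 2.0;
  const double L = box_height;
  const double fvolt = (s_hi > s_lo) ? z_chg * u_volt / (s_hi - s_lo) : 0.0;
  const double excl2 = exclusion_radius * exclusion_radius;
  const double R = pore_radius;

  std::vector<Stream> rng(np);
  for (int i = 0; i < np; ++i)
    stream_init(rng[i], (uint64_t)seed, (uint64_t)(i + 1));

  std::vector<double> x(np), y(np), z(np), zoff(np, 0.0), eta_prev(np);

  // initial placement: uniform in the cylinder, ions respecting exclusion
  for (int i = 0; i < np; ++i) {
    bool ok = false;
    for (int attempt = 0; attempt < 10000 && !ok; ++attempt) {
      double r = R * std::sqrt(unif01(rng[i]));
      double a = 2.0 * M_PI * unif01(rng[i]);
      x[i] = r * std::cos(a);
      y[i] = r * std::sin(a);
      z[i] = (unif01(rng[i]) - 0.5) * L;
      ok = true;
      if (i < n_ions && excl2 > 0.0) {
        for (int j = 0; j < std::min(i, n_ions); ++j) {
          double dz = z[i] - z[j];
          dz -= L * std::round(dz / L);
          double d2 = (x[i] - x[j]) * (x[i] - x[j]) +
                      (y[i] - y[j]) * (y[i] - y[j]) + dz * dz;
          if (d2 < excl2) { ok = false; break; }
        }
      }
    }
    if (!ok) stop("could not place ions without overlap; box too crowded");
    eta_prev[i] = norm1(rng[i]);
  }

  const int n_saved = n_steps / stride + 1;
  NumericMatrix sx(n_saved, np), sy(n_saved, np), sz(n_saved, np),
      szu(n_saved, np);
  int row = 0;
  for (int i = 0; i < np; ++i) {
    sx(row, i) = x[i]; sy(row, i) = y[i]; sz(row, i) = z[i];
    szu(row, i) = z[i];
  }
  row++;

  const double drift_cap = 3.0 * sig;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < np; ++i) {
      double F = 0.0;
      if (i < n_ions) {
        F = interp(gF, grid_lo, grid_h, z[i]);
        if (z[i] > s_lo && z[i] < s_hi) F += fvolt;
      }
      const double drift = D * F * dt;
      if (std::fabs(drift) > drift_cap)
        stop("unstable step: deterministic displacement %.3g A exceeds 3x "
             "step RMS %.3g A at z = %.2f (reduce dt or smooth the "
             "landscape)", std::fabs(drift), sig, z[i]);

      const double eta = norm1(rng[i]);
      double zn = z[i] + drift + 0.5 * sig * (eta_prev[i] + eta);
      double xn = x[i] + sig * norm1(rng[i]);
      double yn = y[i] + sig * norm1(rng[i]);

      // reflect at the cylinder wall
      double rn = std::sqrt(xn * xn + yn * yn);
      if (rn > R && rn > 0.0) {
        double rr = (2.0 * R - rn);
        if (rr < 0.0) rr = 0.0;
        xn *= rr / rn;
        yn *= rr / rn;
      }

      double offn = zoff[i];
      zn = wrap(zn, half, L, offn);

      bool accept = true;
      if (i < n_ions && excl2 > 0.0) {
        for (int j = 0; j < n_ions; ++j) {
          if (j == i) continue;
          double dz = zn - z[j];
          dz -= L * std::round(dz / L);
          double d2 = (xn - x[j]) * (xn - x[j]) +
                      (yn - y[j]) * (yn - y[j]) + dz * dz;
          if (d2 < excl2) { accept = false; break; }
        }
      }
      if (accept) {
        x[i] = xn; y[i] = yn; z[i] = zn; zoff[i] = offn;
      }
      eta_prev[i] = eta;
    }
    if (step % stride == 0) {
      for (int i = 0; i < np; ++i) {
        sx(row, i) = x[i]; sy(row, i) = y[i]; sz(row, i) = z[i];
        szu(row, i) = z[i] + zoff[i];
      }
      row++;
    }
  }

  return List::create(_["x"] = sx, _["y"] = sy, _["z"] = sz,
                      _["z_unwrapped"] = szu);
}

// Nearest path node and perpendicular-style distance for each query point:
// returns the index of the closest node and the distance to it.
// [[Rcpp::export]]
List nearest_node_cpp(NumericVector px, NumericVector py, NumericVector pz,
                      NumericMatrix nodes) {
  const int n = px.size();
  const int m = nodes.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = px[i] - nodes(j, 0);
      double dy = py[i] - nodes(j, 1);
      double dz = pz[i] - nodes(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}
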