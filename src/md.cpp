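// Core molecular-dynamics kernel for the bead-spring chromatin model.
//
// Pair interactions (reduced units, sigma = kBT = 1):
//   - FENE bonds between consecutive beads, diverging at R0
//   - cosine bending on consecutive bond pairs, V = K (1 - cos theta)
//   - WCA excluded volume between all non-attracting pairs
//   - truncated-shifted LJ attraction between flagged (a, b) pairs
//     (PRC1-bound PRE x methylated bead); the attractive pair potential
//     carries its own repulsive core, so WCA is not double-counted there
//   - cosine soft push-off replacing the non-bonded potentials during
//     overlap removal (amplitude ramped by the caller)
//
// Langevin thermostat: friction -m*Gamma*v plus white noise with amplitude
// sqrt(2 m Gamma kBT / dt) applied inside velocity Verlet (the convention of the major MD engines).
// All randomness comes from a self-contained xoshiro256++ generator with a
// polar-method Gaussian, seeded explicitly through splitmix64, so
// trajectories are bitwise reproducible from (seed, inputs) independent of
// the C++ standard library.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const double RMIN = std::pow(2.0, 1.0 / 6.0); // WCA cutoff / LJ minimum

struct Rng {
  uint64_t s[4];

  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed into the xoshiro state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
    have_spare = false;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() { // xoshiro256++
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }

  inline double unif() { // uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  bool have_spare;
  double spare;

  inline double gauss() { // Marsaglia polar
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double fac = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * fac;
    have_spare = true;
    return u * fac;
  }
};

// round-to-nearest without the libm call; arguments are O(box) in size
inline double fast_round(double x) {
  return static_cast<double>(static_cast<long long>(x + (x >= 0 ? 0.5 : -0.5)));
}

struct FF {
  double fene_k, fene_r0, bend_k, ev_eps, bind_eps, bind_cutoff, soft_cutoff;
};

FF read_ff(const List& ff) {
  FF p;
  p.fene_k = as<double>(ff["fene_k"]);
  p.fene_r0 = as<double>(ff["fene_r0"]);
  p.bend_k = as<double>(ff["bend_k"]);
  p.ev_eps = as<double>(ff["ev_eps"]);
  p.bind_eps = as<double>(ff["bind_eps"]);
  p.bind_cutoff = as<double>(ff["bind_cutoff"]);
  p.soft_cutoff = as<double>(ff["soft_cutoff"]);
  return p;
}

inline void min_image(double& dx, double& dy, double& dz, double L) {
  if (L > 0) {
    const double inv = 1.0 / L;
    dx -= L * fast_round(dx * inv);
    dy -= L * fast_round(dy * inv);
    dz -= L * fast_round(dz * inv);
  }
}

// Verlet neighbour list with conservative O(N^2) rebuilds.
struct NeighbourList {
  std::vector<int> ii, jj;
  std::vector<double> ref; // positions at build time
  double skin = 0.3;
  bool valid = false;

  void build(const std::vector<double>& x, int n, double L, double cutoff) {
    ii.clear();
    jj.clear();
    const double rl = cutoff + skin, rl2 = rl * rl;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        min_image(dx, dy, dz, L);
        if (dx * dx + dy * dy + dz * dz < rl2) {
          ii.push_back(i);
          jj.push_back(j);
        }
      }
    }
    ref.assign(x.begin(), x.begin() + 3 * n);
    valid = true;
  }

  bool stale(const std::vector<double>& x, int n) const {
    if (!valid) return true;
    const double half2 = 0.25 * skin * skin;
    for (int i = 0; i < 3 * n; i += 3) {
      double dx = x[i] - ref[i], dy = x[i + 1] - ref[i + 1],
             dz = x[i + 2] - ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > half2) return true;
    }
    return false;
  }
};

// fpair = -(dV/dr)/r so that force on i is fpair * (ri - rj).
inline void pair_wca(double r2, double eps, double& fpair, double& e) {
  const double rc2 = RMIN * RMIN;
  if (r2 >= rc2) { fpair = 0; e = 0; return; }
  double inv2 = 1.0 / r2;
  double sr6 = inv2 * inv2 * inv2;
  e = 4.0 * eps * (sr6 * sr6 - sr6) + eps;
  fpair = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) * inv2;
}

inline void pair_bind(double r2, double eps, double rint, double& fpair,
                      double& e) {
  if (r2 >= rint * rint) { fpair = 0; e = 0; return; }
  double inv2 = 1.0 / r2;
  double sr6 = inv2 * inv2 * inv2;
  double si6 = std::pow(1.0 / rint, 6);
  e = 4.0 * eps * (sr6 * sr6 - sr6) - 4.0 * eps * (si6 * si6 - si6);
  fpair = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) * inv2;
}

inline void pair_soft(double r2, double amp, double rc, double& fpair,
                      double& e) {
  if (r2 >= rc * rc) { fpair = 0; e = 0; return; }
  double r = std::sqrt(r2);
  e = amp * (1.0 + std::cos(M_PI * r / rc));
  // -(dV/dr)/r, with the r -> 0 limit taken analytically
  fpair = (r > 1e-12) ? amp * M_PI / rc * std::sin(M_PI * r / rc) / r
                      : amp * M_PI * M_PI / (rc * rc);
}

// Accumulate forces and potential energy. mode 0 = normal, 1 = soft push-off
// (non-bonded WCA/binding replaced by the soft ramp potential, bonded terms
// kept). Returns potential energy.
double compute_forces(const std::vector<double>& x, int n,
                      const IntegerMatrix& bonds, const IntegerMatrix& angles,
                      const LogicalVector& attr_a, const LogicalVector& attr_b,
                      double L, const FF& p, int mode, double softA,
                      NeighbourList* nl, std::vector<double>& f, long step) {
  std::fill(f.begin(), f.end(), 0.0);
  double epot = 0.0;
  const bool any_attr = (p.bind_eps > 0);
  double cutoff = RMIN;
  if (mode == 1)
    cutoff = p.soft_cutoff;
  else if (any_attr)
    cutoff = std::max(cutoff, p.bind_cutoff);

  // non-bonded pairs
  auto do_pair = [&](int i, int j) {
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    min_image(dx, dy, dz, L);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cutoff * cutoff) return;
    double fpair = 0, e = 0;
    if (mode == 1) {
      pair_soft(r2, softA, p.soft_cutoff, fpair, e);
    } else {
      bool attract = any_attr && ((attr_a[i] && attr_b[j]) ||
                                  (attr_b[i] && attr_a[j]));
      if (attract)
        pair_bind(r2, p.bind_eps, p.bind_cutoff, fpair, e);
      else
        pair_wca(r2, p.ev_eps, fpair, e);
    }
    epot += e;
    f[3 * i] += fpair * dx;
    f[3 * i + 1] += fpair * dy;
    f[3 * i + 2] += fpair * dz;
    f[3 * j] -= fpair * dx;
    f[3 * j + 1] -= fpair * dy;
    f[3 * j + 2] -= fpair * dz;
  };

  if (nl != nullptr) {
    if (nl->stale(x, n)) nl->build(x, n, L, cutoff);
    for (size_t k = 0; k < nl->ii.size(); ++k) do_pair(nl->ii[k], nl->jj[k]);
  } else {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) do_pair(i, j);
  }

  // FENE bonds
  const double r02 = p.fene_r0 * p.fene_r0;
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    min_image(dx, dy, dz, L);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= r02)
      stop("FENE bond %d-%d overextended (r = %.4f >= R0 = %.3f) at step %ld",
           i + 1, j + 1, std::sqrt(r2), p.fene_r0, step);
    double denom = 1.0 - r2 / r02;
    epot += -0.5 * p.fene_k * r02 * std::log(denom);
    double fpair = -p.fene_k / denom; // -(dV/dr)/r
    f[3 * i] += fpair * dx;
    f[3 * i + 1] += fpair * dy;
    f[3 * i + 2] += fpair * dz;
    f[3 * j] -= fpair * dx;
    f[3 * j + 1] -= fpair * dy;
    f[3 * j + 2] -= fpair * dz;
  }

  // bending on bond-vector triplets (i, j, k): theta between r_j - r_i and
  // r_k - r_j, minimum at the straight chain
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
    double ux = x[3 * j] - x[3 * i], uy = x[3 * j + 1] - x[3 * i + 1],
           uz = x[3 * j + 2] - x[3 * i + 2];
    double vx = x[3 * k] - x[3 * j], vy = x[3 * k + 1] - x[3 * j + 1],
           vz = x[3 * k + 2] - x[3 * j + 2];
    min_image(ux, uy, uz, L);
    min_image(vx, vy, vz, L);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    epot += p.bend_k * (1.0 - c);
    // dc/du and dc/dv; F_i = -K dc/du, F_k = +K dc/dv, F_j balances
    double dudx = vx / (nu * nv) - c * ux / (nu * nu);
    double dudy = vy / (nu * nv) - c * uy / (nu * nu);
    double dudz = vz / (nu * nv) - c * uz / (nu * nu);
    double dvdx = ux / (nu * nv) - c * vx / (nv * nv);
    double dvdy = uy / (nu * nv) - c * vy / (nv * nv);
    double dvdz = uz / (nu * nv) - c * vz / (nv * nv);
    f[3 * i] -= p.bend_k * dudx;
    f[3 * i + 1] -= p.bend_k * dudy;
    f[3 * i + 2] -= p.bend_k * dudz;
    f[3 * j] += p.bend_k * (dudx - dvdx);
    f[3 * j + 1] += p.bend_k * (dudy - dvdy);
    f[3 * j + 2] += p.bend_k * (dudz - dvdz);
    f[3 * k] += p.bend_k * dvdx;
    f[3 * k + 1] += p.bend_k * dvdy;
    f[3 * k + 2] += p.bend_k * dvdz;
  }

  return epot;
}

std::vector<double> flatten(const NumericMatrix& m) {
  int n = m.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = m(i, 0);
    x[3 * i + 1] = m(i, 1);
    x[3 * i + 2] = m(i, 2);
  }
  return x;
}

NumericMatrix unflatten(const std::vector<double>& x, int n) {
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = x[3 * i];
    m(i, 1) = x[3 * i + 1];
    m(i, 2) = x[3 * i + 2];
  }
  return m;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerMatrix bonds,
                         IntegerMatrix angles, LogicalVector attr_a,
                         LogicalVector attr_b, double box_side, List ff,
                         int mode, double softA, bool use_nlist) {
  FF p = read_ff(ff);
  int n = pos.nrow();
  std::vector<double> x = flatten(pos), f(3 * n);
  NeighbourList nl;
  compute_forces(x, n, bonds, angles, attr_a, attr_b, box_side, p, mode, softA,
                 use_nlist ? &nl : nullptr, f, 0);
  return unflatten(f, n);
}

// [[Rcpp::export]]
double cpp_energy(NumericMatrix pos, IntegerMatrix bonds, IntegerMatrix angles,
                  LogicalVector attr_a, LogicalVector attr_b, double box_side,
                  List ff, int mode, double softA) {
  FF p = read_ff(ff);
  int n = pos.nrow();
  std::vector<double> x = flatten(pos), f(3 * n);
  return compute_forces(x, n, bonds, angles, attr_a, attr_b, box_side, p, mode,
                        softA, nullptr, f, 0);
}

// Velocity-Verlet Langevin run. The box side moves geometrically from
// box_start to box_end with an affine remap of positions (used by the
// compression stage; box_end == box_start leaves it fixed). In soft mode the
// amplitude ramps linearly from softA_start to softA_end. Frames are sampled
// every `stride` completed steps.
// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos0, NumericMatrix vel0, IntegerMatrix bonds,
                IntegerMatrix angles, LogicalVector attr_a,
                LogicalVector attr_b, LogicalVector mobile, double box_start,
                double box_end, List ff, double kBT, double mass, double gamma,
                double dt, int n_steps, int stride, int mode,
                double softA_start, double softA_end, double seed,
                bool use_nlist, bool thermostat) {
  FF p = read_ff(ff);
  const int n = pos0.nrow();
  std::vector<double> x = flatten(pos0), v = flatten(vel0), f(3 * n);
  Rng rng(static_cast<uint64_t>(seed));
  NeighbourList nl;
  NeighbourList* nlp = use_nlist ? &nl : nullptr;

  double L = box_start;
  const double shrink =
      (box_end != box_start) ? std::pow(box_end / box_start, 1.0 / n_steps)
                             : 1.0;
  const double noise_amp =
      thermostat ? std::sqrt(2.0 * mass * gamma * kBT / dt) : 0.0;
  const double fric = thermostat ? mass * gamma : 0.0;

  auto langevin = [&](double softA) {
    double e = compute_forces(x, n, bonds, angles, attr_a, attr_b, L, p, mode,
                              softA, nlp, f, 0);
    (void)e;
    if (thermostat || gamma > 0) {
      for (int i = 0; i < n; ++i) {
        if (!mobile[i]) continue;
        for (int d = 0; d < 3; ++d) {
          f[3 * i + d] += -fric * v[3 * i + d] + noise_amp * rng.gauss();
        }
      }
    }
  };

  double softA = softA_start;
  langevin(softA);

  std::vector<NumericMatrix> frames;
  std::vector<int> frame_steps;
  const double half = 0.5 * dt / mass;

  for (int s = 0; s < n_steps; ++s) {
    if (shrink != 1.0) {
      L *= shrink;
      for (int i = 0; i < 3 * n; ++i) x[i] *= shrink;
      nl.valid = false;
    }
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int d = 0; d < 3; ++d) {
        v[3 * i + d] += half * f[3 * i + d];
        x[3 * i + d] += dt * v[3 * i + d];
      }
    }
    softA = softA_start + (softA_end - softA_start) * (s + 1.0) / n_steps;
    langevin(softA);
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int d = 0; d < 3; ++d) v[3 * i + d] += half * f[3 * i + d];
    }
    if (stride > 0 && (s + 1) % stride == 0) {
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i]))
          stop("non-finite coordinate for bead %d at step %d", i / 3 + 1,
               s + 1);
      frames.push_back(unflatten(x, n));
      frame_steps.push_back(s + 1);
    }
  }
  for (int i = 0; i < 3 * n; ++i)
    if (!std::isfinite(x[i]))
      stop("non-finite coordinate for bead %d after run", i / 3 + 1);

  return List::create(
      _["positions"] = unflatten(x, n), _["velocities"] = unflatten(v, n),
      _["box_side"] = L, _["frames"] = wrap(frames),
      _["frame_steps"] = wrap(frame_steps), _["n_steps"] = n_steps);
}

// Minimum-image distance from each row of `pos` (excluding row `site`) to
// the site row; used by the binding-calibration bound/unbound classifier.
// [[Rcpp::export]]
NumericVector cpp_dist_to_site(NumericMatrix pos, int site, double box_side) {
  int n = pos.nrow();
  NumericVector out(n - 1);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (i == site) continue;
    double dx = pos(i, 0) - pos(site, 0);
    double dy = pos(i, 1) - pos(site, 1);
    double dz = pos(i, 2) - pos(site, 2);
    min_image(dx, dy, dz, box_side);
    out[k++] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return out;
}

// Minimum pair distance under minimum image, optionally skipping bonded
// pairs; used to verify overlap removal after the soft push-off.
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix pos, IntegerMatrix bonds,
                         double box_side, bool exclude_bonded) {
  int n = pos.nrow();
  std::vector<std::vector<bool>> bonded;
  if (exclude_bonded) {
    bonded.assign(n, std::vector<bool>(n, false));
    for (int b = 0; b < bonds.nrow(); ++b) {
      bonded[bonds(b, 0)][bonds(b, 1)] = true;
      bonded[bonds(b, 1)][bonds(b, 0)] = true;
    }
  }
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (exclude_bonded && bonded[i][j]) continue;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      min_image(dx, dy, dz, box_side);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < best) best = r;
    }
  }
  return best;
}
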