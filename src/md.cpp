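#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <utility>

using namespace Rcpp;

namespace {

// Post lattice: infinite cylinders parallel to x, centers on a square lattice
// in the yz-plane with spacing Sp; Dp is the *bare* post diameter entering
// the shifted WCA interaction.
struct Geom {
  bool on = false;
  double Sp = 0.0, Dp = 0.0, oy = 0.0, oz = 0.0;
};

struct FF {
  double eps, sigma, kappa, R0, bend; // bend = b * eps (energy per unit (1 - cos))
};

struct Model {
  int N;
  bool circular;
  FF ff;
  Geom g;
  double rc, rc2;
  std::vector<double> x, y, z, fx, fy, fz;
  double ebond, ebend, epair, epost;
  int bad_bond, bad_post_bead, bad_angle;

  Model(int N_, bool circ, FF ff_, Geom g_)
      : N(N_), circular(circ), ff(ff_), g(g_) {
    rc = std::pow(2.0, 1.0 / 6.0) * ff.sigma;
    rc2 = rc * rc;
    x.assign(N, 0.0); y.assign(N, 0.0); z.assign(N, 0.0);
    fx.assign(N, 0.0); fy.assign(N, 0.0); fz.assign(N, 0.0);
  }

  int nbonds() const { return circular ? N : N - 1; }

  inline void wca_pair(int i, int j) {
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return;
    double s2 = ff.sigma * ff.sigma / r2;
    double s6 = s2 * s2 * s2;
    epair += 4.0 * ff.eps * (s6 * s6 - s6) + ff.eps;
    double fr = 24.0 * ff.eps * (2.0 * s6 * s6 - s6) / r2;
    fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
    fx[j] += fr * dx; fy[j] += fr * dy; fz[j] += fr * dz;
  }

  // Returns false (with bad_* set) on an unphysical configuration.
  bool compute(const std::vector<std::pair<int, int>>* nl) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    ebond = ebend = epair = epost = 0.0;
    bad_bond = bad_post_bead = bad_angle = -1;

    const int nb = nbonds();
    const double R02 = ff.R0 * ff.R0;
    for (int k = 0; k < nb; ++k) {
      int i = k, j = (k + 1) % N;
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= R02) { bad_bond = k; return false; }
      double u = r2 / R02;
      ebond += -0.5 * ff.kappa * R02 * std::log1p(-u);
      double c = ff.kappa / (1.0 - u);
      // FENE pulls the pair together
      fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
      fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
    }

    if (ff.bend > 0.0) {
      int na = circular ? N : N - 2;
      for (int a = 0; a < na; ++a) {
        int j = circular ? a : a + 1;          // central bead
        int i = (j - 1 + N) % N, k2 = (j + 1) % N;
        double ax = x[j] - x[i], ay = y[j] - y[i], az = z[j] - z[i];
        double bx = x[k2] - x[j], by = y[k2] - y[j], bz = z[k2] - z[j];
        double A2 = ax * ax + ay * ay + az * az;
        double B2 = bx * bx + by * by + bz * bz;
        if (A2 < 1e-20 || B2 < 1e-20) { bad_angle = j; return false; }
        double A = std::sqrt(A2), B = std::sqrt(B2);
        double cphi = (ax * bx + ay * by + az * bz) / (A * B);
        ebend += ff.bend * (1.0 - cphi);
        double k = ff.bend;
        double dax = bx / (A * B) - cphi * ax / A2;
        double day = by / (A * B) - cphi * ay / A2;
        double daz = bz / (A * B) - cphi * az / A2;
        double dbx = ax / (A * B) - cphi * bx / B2;
        double dby = ay / (A * B) - cphi * by / B2;
        double dbz = az / (A * B) - cphi * bz / B2;
        fx[i] -= k * dax; fy[i] -= k * day; fz[i] -= k * daz;
        fx[k2] += k * dbx; fy[k2] += k * dby; fz[k2] += k * dbz;
        fx[j] += k * (dax - dbx);
        fy[j] += k * (day - dby);
        fz[j] += k * (daz - dbz);
      }
    }

    // Non-bonded WCA over all pairs (bonded neighbours included once, here).
    if (nl != nullptr) {
      for (const auto& p : *nl) wca_pair(p.first, p.second);
    } else {
      for (int i = 0; i < N - 1; ++i)
        for (int j = i + 1; j < N; ++j) wca_pair(i, j);
    }

    if (g.on) {
      // Only the four posts at the vertices of the bead's interstitial cell
      // can be in range (guaranteed for w_p >= 0, Sp > Dp/2 + rc).
      for (int i = 0; i < N; ++i) {
        double py = y[i] - g.oy, pz = z[i] - g.oz;
        double ci = std::floor(py / g.Sp), cj = std::floor(pz / g.Sp);
        for (int a = 0; a <= 1; ++a) {
          for (int b = 0; b <= 1; ++b) {
            double cy = (ci + a) * g.Sp + g.oy;
            double cz = (cj + b) * g.Sp + g.oz;
            double dy = y[i] - cy, dz = z[i] - cz;
            double r = std::sqrt(dy * dy + dz * dz);
            double s = r - 0.5 * g.Dp;
            if (s >= rc) continue;
            if (s <= 0.0 || r <= 0.0) { bad_post_bead = i; return false; }
            double inv = ff.sigma / s;
            double s6 = inv * inv;
            s6 = s6 * s6 * s6;
            epost += 4.0 * ff.eps * (s6 * s6 - s6) + ff.eps;
            double fmag = 24.0 * ff.eps * (2.0 * s6 * s6 - s6) / s;
            // posts are x-invariant: force strictly in the yz-plane
            fy[i] += fmag * dy / r;
            fz[i] += fmag * dz / r;
          }
        }
      }
    }
    return true;
  }

  double epot() const { return ebond + ebend + epair + epost; }
};

// Verlet neighbour list over all bead pairs, rebuilt when any bead has moved
// more than skin/2 since the last build.
struct NList {
  double skin, rl2, halfskin2;
  std::vector<std::pair<int, int>> pairs;
  std::vector<double> bx, by, bz;

  NList(double skin_, double rc) : skin(skin_) {
    double rl = rc + skin;
    rl2 = rl * rl;
    halfskin2 = 0.25 * skin * skin;
  }

  void build(const Model& m) {
    pairs.clear();
    for (int i = 0; i < m.N - 1; ++i) {
      for (int j = i + 1; j < m.N; ++j) {
        double dx = m.x[j] - m.x[i], dy = m.y[j] - m.y[i], dz = m.z[j] - m.z[i];
        if (dx * dx + dy * dy + dz * dz < rl2) pairs.emplace_back(i, j);
      }
    }
    bx = m.x; by = m.y; bz = m.z;
  }

  bool stale(const Model& m) const {
    for (int i = 0; i < m.N; ++i) {
      double dx = m.x[i] - bx[i], dy = m.y[i] - by[i], dz = m.z[i] - bz[i];
      if (dx * dx + dy * dy + dz * dz > halfskin2) return true;
    }
    return false;
  }
};

void load_positions(Model& m, const NumericMatrix& pos) {
  for (int i = 0; i < m.N; ++i) {
    m.x[i] = pos(i, 0); m.y[i] = pos(i, 1); m.z[i] = pos(i, 2);
  }
}

void fail_state(const Model& m, int step) {
  if (m.bad_bond >= 0)
    stop("integration failure at step %d: bond %d reached the maximal FENE length",
         step, m.bad_bond + 1);
  if (m.bad_post_bead >= 0)
    stop("integration failure at step %d: bead %d inside a post core",
         step, m.bad_post_bead + 1);
  stop("integration failure at step %d: zero-length bond at bead %d",
       step, m.bad_angle + 1);
}

} // namespace

// [[Rcpp::export]]
List np_energy_forces(NumericMatrix pos, bool circular,
                      double eps, double sigma, double kappa, double R0,
                      double bend,
                      bool has_array, double Sp, double Dp,
                      double oy, double oz) {
  int N = pos.nrow();
  FF ff{eps, sigma, kappa, R0, bend};
  Geom g; g.on = has_array; g.Sp = Sp; g.Dp = Dp; g.oy = oy; g.oz = oz;
  Model m(N, circular, ff, g);
  load_positions(m, pos);
  if (!m.compute(nullptr)) fail_state(m, 0);
  NumericMatrix f(N, 3);
  for (int i = 0; i < N; ++i) {
    f(i, 0) = m.fx[i]; f(i, 1) = m.fy[i]; f(i, 2) = m.fz[i];
  }
  return List::create(_["total"] = m.epot(), _["bond"] = m.ebond,
                      _["bend"] = m.ebend, _["pair"] = m.epair,
                      _["post"] = m.epost, _["forces"] = f);
}

// Leap-frog integrator; thermostat: 0 = none (NVE), 1 = Nose-Hoover,
// 2 = Langevin (BBK). Bead mass and kB are 1 in reduced units.
// [[Rcpp::export]]
List np_md_run(NumericMatrix pos, NumericMatrix vel, bool circular,
               double eps, double sigma, double kappa, double R0, double bend,
               bool has_array, double Sp, double Dp, double oy, double oz,
               double dt, int nsteps, int sample_every,
               int thermostat, double temp, double tau, double gamma,
               int seed, double skin, double chi0) {
  int N = pos.nrow();
  FF ff{eps, sigma, kappa, R0, bend};
  Geom g; g.on = has_array; g.Sp = Sp; g.Dp = Dp; g.oy = oy; g.oz = oz;
  Model m(N, circular, ff, g);
  load_positions(m, pos);

  NList nl(skin, m.rc);
  nl.build(m);
  if (!m.compute(&nl.pairs)) fail_state(m, 0);

  // half-step-behind velocities from the supplied on-step velocities
  std::vector<double> vhx(N), vhy(N), vhz(N);
  for (int i = 0; i < N; ++i) {
    vhx[i] = vel(i, 0) - 0.5 * dt * m.fx[i];
    vhy[i] = vel(i, 1) - 0.5 * dt * m.fy[i];
    vhz[i] = vel(i, 2) - 0.5 * dt * m.fz[i];
  }

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::normal_distribution<double> nd(0.0, 1.0);

  int nsamp = (sample_every > 0) ? nsteps / sample_every : 0;
  NumericVector frames(static_cast<R_xlen_t>(nsamp) * N * 3);
  frames.attr("dim") = IntegerVector::create(N, 3, nsamp);
  NumericVector pot(nsamp), kin(nsamp), tinst(nsamp);
  IntegerVector steps_out(nsamp);

  std::vector<double> vpx(N), vpy(N), vpz(N), vfx(N), vfy(N), vfz(N);
  double chi = chi0;
  int isamp = 0;

  for (int step = 1; step <= nsteps; ++step) {
    // velocity update with forces at the current positions
    if (thermostat == 0) {
      for (int i = 0; i < N; ++i) {
        vpx[i] = vhx[i] + dt * m.fx[i];
        vpy[i] = vhy[i] + dt * m.fy[i];
        vpz[i] = vhz[i] + dt * m.fz[i];
        vfx[i] = 0.5 * (vhx[i] + vpx[i]);
        vfy[i] = 0.5 * (vhy[i] + vpy[i]);
        vfz[i] = 0.5 * (vhz[i] + vpz[i]);
      }
    } else if (thermostat == 1) {
      // iterative leap-frog Nose-Hoover: chi'(t) = (T(t)/T0 - 1)/tau^2
      for (int i = 0; i < N; ++i) {
        vfx[i] = vhx[i] + 0.5 * dt * m.fx[i];
        vfy[i] = vhy[i] + 0.5 * dt * m.fy[i];
        vfz[i] = vhz[i] + 0.5 * dt * m.fz[i];
      }
      double chi_new = chi;
      for (int it = 0; it < 3; ++it) {
        double k2 = 0.0;
        for (int i = 0; i < N; ++i)
          k2 += vfx[i] * vfx[i] + vfy[i] * vfy[i] + vfz[i] * vfz[i];
        double Ti = k2 / (3.0 * N);
        chi_new = chi + dt * (Ti / temp - 1.0) / (tau * tau);
        double chimid = 0.5 * (chi + chi_new);
        for (int i = 0; i < N; ++i) {
          vpx[i] = vhx[i] + dt * (m.fx[i] - chimid * vfx[i]);
          vpy[i] = vhy[i] + dt * (m.fy[i] - chimid * vfy[i]);
          vpz[i] = vhz[i] + dt * (m.fz[i] - chimid * vfz[i]);
          vfx[i] = 0.5 * (vhx[i] + vpx[i]);
          vfy[i] = 0.5 * (vhy[i] + vpy[i]);
          vfz[i] = 0.5 * (vhz[i] + vpz[i]);
        }
      }
      chi = chi_new;
    } else {
      // BBK leap-frog Langevin
      double denom = 1.0 + 0.5 * gamma * dt;
      double fac = 1.0 - 0.5 * gamma * dt;
      double sd = std::sqrt(2.0 * gamma * temp / dt);
      for (int i = 0; i < N; ++i) {
        vpx[i] = (fac * vhx[i] + dt * (m.fx[i] + sd * nd(rng))) / denom;
        vpy[i] = (fac * vhy[i] + dt * (m.fy[i] + sd * nd(rng))) / denom;
        vpz[i] = (fac * vhz[i] + dt * (m.fz[i] + sd * nd(rng))) / denom;
        vfx[i] = 0.5 * (vhx[i] + vpx[i]);
        vfy[i] = 0.5 * (vhy[i] + vpy[i]);
        vfz[i] = 0.5 * (vhz[i] + vpz[i]);
      }
    }

    // sample the state at the current time (positions + on-step velocities)
    if (sample_every > 0 && step % sample_every == 0 && isamp < nsamp) {
      double k2 = 0.0;
      for (int i = 0; i < N; ++i) {
        frames[isamp * N * 3 + i] = m.x[i];
        frames[isamp * N * 3 + N + i] = m.y[i];
        frames[isamp * N * 3 + 2 * N + i] = m.z[i];
        k2 += vfx[i] * vfx[i] + vfy[i] * vfy[i] + vfz[i] * vfz[i];
      }
      double U = m.epot();
      if (!std::isfinite(U) || !std::isfinite(k2))
        stop("integration failure at step %d: non-finite energy", step);
      pot[isamp] = U;
      kin[isamp] = 0.5 * k2;
      tinst[isamp] = k2 / (3.0 * N);
      steps_out[isamp] = step;
      ++isamp;
    }

    for (int i = 0; i < N; ++i) {
      m.x[i] += dt * vpx[i];
      m.y[i] += dt * vpy[i];
      m.z[i] += dt * vpz[i];
    }
    std::swap(vhx, vpx); std::swap(vhy, vpy); std::swap(vhz, vpz);

    if (nl.stale(m)) nl.build(m);
    if (!m.compute(&nl.pairs)) fail_state(m, step);
  }

  NumericMatrix pos_out(N, 3), vel_out(N, 3);
  for (int i = 0; i < N; ++i) {
    pos_out(i, 0) = m.x[i]; pos_out(i, 1) = m.y[i]; pos_out(i, 2) = m.z[i];
    // on-step estimate: vh is now the velocity half a step behind the final
    // positions; pair it with the final forces for an O(dt^2) on-step value
    vel_out(i, 0) = vhx[i] + 0.5 * dt * m.fx[i];
    vel_out(i, 1) = vhy[i] + 0.5 * dt * m.fy[i];
    vel_out(i, 2) = vhz[i] + 0.5 * dt * m.fz[i];
  }

  return List::create(_["frames"] = frames, _["steps"] = steps_out,
                      _["potential"] = pot, _["kinetic"] = kin,
                      _["temperature"] = tinst,
                      _["positions"] = pos_out, _["velocities"] = vel_out,
                      _["chi"] = chi);
}
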