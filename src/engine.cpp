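// Compiled core of the flocking simulator: candidate-pair search in the
// periodic box, force evaluation, explicit midpoint integration with optional
// noise and delayed forces, and the forward-Euler two-agent encounter.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double min_image1(double dx, double L, double halfL) {
  if (dx > halfL) dx -= L; else if (dx < -halfL) dx += L;
  return dx;
}

// Map one coordinate into [0, L); cheap for the common one-box overshoot,
// exact for arbitrary finite values.
static inline double wrap1(double v, double L) {
  if (v >= L) { v -= L; if (v >= L) { v -= L * std::floor(v / L); } }
  else if (v < 0) { v += L; if (v < 0) { v -= L * std::floor(v / L); } }
  if (v >= L) v = 0.0;
  else if (v < 0) v = 0.0;
  return v;
}

struct Cand { std::vector<int> i, j; };

// All unordered pairs with minimum-image distance < Rlist (strict), i < j.
// Cell grid with cell side L/floor(L/Rlist) when floor(L/Rlist) >= 3,
// otherwise a plain double loop (both exact).
static void build_candidates(const double *x, const double *y, const double *z,
                             int N, double L, double Rlist, Cand &c) {
  c.i.clear(); c.j.clear();
  const double R2 = Rlist * Rlist, halfL = 0.5 * L;
  int m = (int)std::floor(L / Rlist);
  if (m < 3) {
    for (int a = 0; a < N; ++a)
      for (int b = a + 1; b < N; ++b) {
        double dx = min_image1(x[a] - x[b], L, halfL);
        double dy = min_image1(y[a] - y[b], L, halfL);
        double dz = min_image1(z[a] - z[b], L, halfL);
        if (dx * dx + dy * dy + dz * dz < R2) { c.i.push_back(a); c.j.push_back(b); }
      }
    return;
  }
  const double cs = L / m;
  const int ncell = m * m * m;
  std::vector<int> head(ncell, -1), nxt(N);
  for (int a = 0; a < N; ++a) {
    int ix = (int)(x[a] / cs); if (ix >= m) ix = m - 1; if (ix < 0) ix = 0;
    int iy = (int)(y[a] / cs); if (iy >= m) iy = m - 1; if (iy < 0) iy = 0;
    int iz = (int)(z[a] / cs); if (iz >= m) iz = m - 1; if (iz < 0) iz = 0;
    int cell = ix + m * (iy + m * iz);
    nxt[a] = head[cell]; head[cell] = a;
  }
  // 13 half-offsets: each neighbouring cell pair visited exactly once
  // (distinct for m >= 3 since offset differences stay below m in magnitude).
  static const int off[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
  for (int iz = 0; iz < m; ++iz)
    for (int iy = 0; iy < m; ++iy)
      for (int ix = 0; ix < m; ++ix) {
        int c0 = ix + m * (iy + m * iz);
        for (int a = head[c0]; a != -1; a = nxt[a])
          for (int b = nxt[a]; b != -1; b = nxt[b]) {
            double dx = min_image1(x[a] - x[b], L, halfL);
            double dy = min_image1(y[a] - y[b], L, halfL);
            double dz = min_image1(z[a] - z[b], L, halfL);
            if (dx * dx + dy * dy + dz * dz < R2) {
              if (a < b) { c.i.push_back(a); c.j.push_back(b); }
              else       { c.i.push_back(b); c.j.push_back(a); }
            }
          }
        for (int k = 0; k < 13; ++k) {
          int jx = (ix + off[k][0] + m) % m;
          int jy = (iy + off[k][1] + m) % m;
          int jz = (iz + off[k][2] + m) % m;
          int c1 = jx + m * (jy + m * jz);
          for (int a = head[c0]; a != -1; a = nxt[a])
            for (int b = head[c1]; b != -1; b = nxt[b]) {
              double dx = min_image1(x[a] - x[b], L, halfL);
              double dy = min_image1(y[a] - y[b], L, halfL);
              double dz = min_image1(z[a] - z[b], L, halfL);
              if (dx * dx + dy * dy + dz * dz < R2) {
                if (a < b) { c.i.push_back(a); c.j.push_back(b); }
                else       { c.i.push_back(b); c.j.push_back(a); }
              }
            }
        }
      }
}

// Speed relaxation toward v0 plus inverse-square repulsion below the true
// cutoff R, summed over candidate pairs. Returns false on coincident agents.
static bool eval_forces(const double *x, const double *y, const double *z,
                        const double *vx, const double *vy, const double *vz,
                        int N, double L, double v0, double tau, double mass,
                        double cc, double R, const Cand &cand,
                        double *fx, double *fy, double *fz) {
  const double halfL = 0.5 * L, R2 = R * R;
  const double mt = std::isfinite(tau) ? mass / tau : 0.0;
  for (int a = 0; a < N; ++a) {
    double s2 = vx[a] * vx[a] + vy[a] * vy[a] + vz[a] * vz[a];
    if (s2 > 0.0) {
      double s = std::sqrt(s2);
      double fac = mt * (v0 - s) / s;
      fx[a] = fac * vx[a]; fy[a] = fac * vy[a]; fz[a] = fac * vz[a];
    } else {
      fx[a] = 0.0; fy[a] = 0.0; fz[a] = 0.0;  // heading undefined at |v| = 0
    }
  }
  const size_t np = cand.i.size();
  for (size_t k = 0; k < np; ++k) {
    const int a = cand.i[k], b = cand.j[k];
    double dx = min_image1(x[a] - x[b], L, halfL);
    double dy = min_image1(y[a] - y[b], L, halfL);
    double dz = min_image1(z[a] - z[b], L, halfL);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= R2) continue;
    if (r2 <= 0.0) return false;
    double w = cc / (r2 * std::sqrt(r2));  // c/r^2 along the unit separation
    fx[a] += w * dx; fy[a] += w * dy; fz[a] += w * dz;
    fx[b] -= w * dx; fy[b] -= w * dy; fz[b] -= w * dz;
  }
  return true;
}

// Marsaglia's method: uniform direction on the unit sphere from two
// uniforms, cheaper than normalizing three normal deviates.
static inline void draw_unit(double &ux, double &uy, double &uz) {
  double u, v, s;
  do {
    u = 2.0 * unif_rand() - 1.0;
    v = 2.0 * unif_rand() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s < 1e-300);
  double f = 2.0 * std::sqrt(1.0 - s);
  ux = u * f; uy = v * f; uz = 1.0 - 2.0 * s;
}

// Exact neighbour pairs (min-image distance < R) for the R-level API.
// [[Rcpp::export]]
List neighbor_pairs_cpp(NumericMatrix pos, double L, double R) {
  int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N);
  for (int a = 0; a < N; ++a) { x[a] = pos(a, 0); y[a] = pos(a, 1); z[a] = pos(a, 2); }
  Cand c;
  build_candidates(x.data(), y.data(), z.data(), N, L, R, c);
  int np = (int)c.i.size();
  IntegerVector ii(np), jj(np);
  NumericMatrix disp(np, 3);
  NumericVector dist(np);
  const double halfL = 0.5 * L;
  for (int k = 0; k < np; ++k) {
    int a = c.i[k], b = c.j[k];
    double dx = min_image1(x[a] - x[b], L, halfL);
    double dy = min_image1(y[a] - y[b], L, halfL);
    double dz = min_image1(z[a] - z[b], L, halfL);
    ii[k] = a + 1; jj[k] = b + 1;
    disp(k, 0) = dx; disp(k, 1) = dy; disp(k, 2) = dz;
    dist[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["disp"] = disp, _["dist"] = dist);
}

// Explicit midpoint integration of the flocking equations of motion.
// Noise enters as velocity impulses (never delayed); with use_history the
// deterministic forces are replaced by records taken delay_steps earlier
// (clamped to the oldest record during warm-up).
// [[Rcpp::export]]
List run_sim_cpp(NumericMatrix pos0, NumericMatrix vel0,
                 double L, double v0, double tau, double mass, double cc,
                 double R, double xi, double dt,
                 int n_steps, int record_every,
                 int delay_steps, bool use_history, bool sqrt_noise,
                 double skin, bool record_traj) {
  const int N = pos0.nrow();
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N);
  for (int a = 0; a < N; ++a) {
    x[a] = pos0(a, 0); y[a] = pos0(a, 1); z[a] = pos0(a, 2);
    vx[a] = vel0(a, 0); vy[a] = vel0(a, 1); vz[a] = vel0(a, 2);
  }
  const double halfdt = 0.5 * dt;
  double amp_h = 0.0, amp_f = 0.0;
  const bool noisy = xi > 0.0;
  if (noisy) {
    amp_h = sqrt_noise ? xi * std::sqrt(halfdt) / mass : xi * halfdt / mass;
    amp_f = sqrt_noise ? xi * std::sqrt(dt) / mass : xi * dt / mass;
  }
  const double Rlist = R + skin;
  Cand cand;
  std::vector<double> f1x(N), f1y(N), f1z(N), f2x(N), f2y(N), f2z(N);
  std::vector<double> vhx(N), vhy(N), vhz(N), phx(N), phy(N), phz(N);
  std::vector<double> dpx(N, 0.0), dpy(N, 0.0), dpz(N, 0.0);
  const int cap = delay_steps + 1;
  std::vector< std::vector<double> > h1, h2;
  if (use_history) {
    h1.assign(cap, std::vector<double>(3 * N, 0.0));
    h2.assign(cap, std::vector<double>(3 * N, 0.0));
  }
  bool need_build = true;
  long n_rebuild = 0, n_clamped = 0;
  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_E(n_rec);
  List traj_p(record_traj ? n_rec : 0), traj_v(record_traj ? n_rec : 0);
  int irec = 0;
  const double inv_nv0 = 1.0 / (N * v0);

  // record the state at step `s` (time offset s*dt)
  auto record = [&](int s) {
    double sx = 0, sy = 0, sz = 0;
    for (int a = 0; a < N; ++a) { sx += vx[a]; sy += vy[a]; sz += vz[a]; }
    double E = std::sqrt(sx * sx + sy * sy + sz * sz) * inv_nv0;
    if (!std::isfinite(E))
      stop("non-finite state at step %d (time offset %g s)", s, s * dt);
    rec_t[irec] = s * dt; rec_E[irec] = E;
    if (record_traj) {
      NumericMatrix P(N, 3), V(N, 3);
      for (int a = 0; a < N; ++a) {
        P(a, 0) = x[a]; P(a, 1) = y[a]; P(a, 2) = z[a];
        V(a, 0) = vx[a]; V(a, 1) = vy[a]; V(a, 2) = vz[a];
      }
      traj_p[irec] = P; traj_v[irec] = V;
    }
    ++irec;
  };
  record(0);

  for (int s = 0; s < n_steps; ++s) {
    // rebuild the candidate list before any pair can have drifted inside R
    if (!need_build) {
      double d1 = 0, d2 = 0;
      for (int a = 0; a < N; ++a) {
        double dd = dpx[a] * dpx[a] + dpy[a] * dpy[a] + dpz[a] * dpz[a];
        if (dd > d1) { d2 = d1; d1 = dd; } else if (dd > d2) d2 = dd;
      }
      if (std::sqrt(d1) + std::sqrt(d2) > 0.5 * skin) need_build = true;
    }
    if (need_build) {
      build_candidates(x.data(), y.data(), z.data(), N, L, Rlist, cand);
      std::fill(dpx.begin(), dpx.end(), 0.0);
      std::fill(dpy.begin(), dpy.end(), 0.0);
      std::fill(dpz.begin(), dpz.end(), 0.0);
      need_build = false; ++n_rebuild;
    }

    if (!eval_forces(x.data(), y.data(), z.data(), vx.data(), vy.data(), vz.data(),
                     N, L, v0, tau, mass, cc, R, cand,
                     f1x.data(), f1y.data(), f1z.data()))
      stop("coincident agents at step %d", s);
    const double *u1x = f1x.data(), *u1y = f1y.data(), *u1z = f1z.data();
    if (use_history) {
      std::vector<double> &slot = h1[s % cap];
      for (int a = 0; a < N; ++a) {
        slot[a] = f1x[a]; slot[N + a] = f1y[a]; slot[2 * N + a] = f1z[a];
      }
      int idx = s - delay_steps;
      if (idx < 0) { idx = 0; ++n_clamped; }
      std::vector<double> &use = h1[idx % cap];
      u1x = use.data(); u1y = use.data() + N; u1z = use.data() + 2 * N;
    }

    const double hm = halfdt / mass;
    for (int a = 0; a < N; ++a) {
      vhx[a] = vx[a] + u1x[a] * hm;
      vhy[a] = vy[a] + u1y[a] * hm;
      vhz[a] = vz[a] + u1z[a] * hm;
      phx[a] = x[a] + vx[a] * halfdt;
      phy[a] = y[a] + vy[a] * halfdt;
      phz[a] = z[a] + vz[a] * halfdt;
    }
    if (noisy) {
      double ux, uy, uz;
      for (int a = 0; a < N; ++a) {
        draw_unit(ux, uy, uz);
        vhx[a] += amp_h * ux; vhy[a] += amp_h * uy; vhz[a] += amp_h * uz;
      }
    }

    if (!eval_forces(phx.data(), phy.data(), phz.data(),
                     vhx.data(), vhy.data(), vhz.data(),
                     N, L, v0, tau, mass, cc, R, cand,
                     f2x.data(), f2y.data(), f2z.data()))
      stop("coincident agents at step %d (half step)", s);
    const double *u2x = f2x.data(), *u2y = f2y.data(), *u2z = f2z.data();
    if (use_history) {
      std::vector<double> &slot = h2[s % cap];
      for (int a = 0; a < N; ++a) {
        slot[a] = f2x[a]; slot[N + a] = f2y[a]; slot[2 * N + a] = f2z[a];
      }
      int idx = s - delay_steps; if (idx < 0) idx = 0;
      std::vector<double> &use = h2[idx % cap];
      u2x = use.data(); u2y = use.data() + N; u2z = use.data() + 2 * N;
    }

    const double fm = dt / mass;
    for (int a = 0; a < N; ++a) {
      vx[a] += u2x[a] * fm; vy[a] += u2y[a] * fm; vz[a] += u2z[a] * fm;
    }
    if (noisy) {
      double ux, uy, uz;
      for (int a = 0; a < N; ++a) {
        draw_unit(ux, uy, uz);
        vx[a] += amp_f * ux; vy[a] += amp_f * uy; vz[a] += amp_f * uz;
      }
    }
    for (int a = 0; a < N; ++a) {
      double mx = vhx[a] * dt, my = vhy[a] * dt, mz = vhz[a] * dt;
      x[a] = wrap1(x[a] + mx, L);
      y[a] = wrap1(y[a] + my, L);
      z[a] = wrap1(z[a] + mz, L);
      dpx[a] += mx; dpy[a] += my; dpz[a] += mz;
    }

    if ((s + 1) % record_every == 0) record(s + 1);
  }

  NumericMatrix P(N, 3), V(N, 3);
  for (int a = 0; a < N; ++a) {
    P(a, 0) = x[a]; P(a, 1) = y[a]; P(a, 2) = z[a];
    V(a, 0) = vx[a]; V(a, 1) = vy[a]; V(a, 2) = vz[a];
  }
  return List::create(
    _["times"] = rec_t, _["efficiency"] = rec_E,
    _["positions"] = P, _["velocities"] = V,
    _["n_rebuild"] = (double)n_rebuild, _["n_clamped"] = (double)n_clamped,
    _["traj_positions"] = traj_p, _["traj_velocities"] = traj_v);
}

// Symmetric two-agent encounter: forward Euler, no cutoff, no periodic box.
// Agents start mirror-symmetric (rotation by pi about the y axis), projected
// (xy) separation D0, velocity angle phi; integration stops when the
// projected separation reaches Dstop.
// [[Rcpp::export]]
List run_encounter_cpp(double d, double phi_deg, double dt, double D0,
                       double Dstop, double v0, double tau, double cc,
                       double mass, double max_time, int sym_check_every) {
  const double phi = phi_deg * M_PI / 180.0;
  const double sh = std::sin(0.5 * phi), ch = std::cos(0.5 * phi);
  double x1 = -0.5 * D0, y1 = 0.0, z1 = 0.5 * d;
  double x2 = 0.5 * D0, y2 = 0.0, z2 = -0.5 * d;
  double v1x = v0 * sh, v1y = v0 * ch, v1z = 0.0;
  double v2x = -v0 * sh, v2y = v0 * ch, v2z = 0.0;
  const double p0 = mass * std::sqrt((v1x + v2x) * (v1x + v2x) +
                                     (v1y + v2y) * (v1y + v2y) +
                                     (v1z + v2z) * (v1z + v2z));
  const double mt = std::isfinite(tau) ? mass / tau : 0.0;
  const long max_steps = (long)std::ceil(max_time / dt);
  const double stop2 = Dstop * Dstop;
  double closest2 = std::numeric_limits<double>::infinity();
  double max_asym = 0.0;
  long s = 0;
  for (; s < max_steps; ++s) {
    double dx = x1 - x2, dy = y1 - y2, dz = z1 - z2;
    double hor2 = dx * dx + dy * dy;
    if (hor2 >= stop2) break;
    double r2 = hor2 + dz * dz;
    if (r2 < closest2) closest2 = r2;
    if (r2 <= 0.0) stop("coincident agents in encounter at step %ld", s);
    double w = cc / (r2 * std::sqrt(r2));
    double f1x = w * dx, f1y = w * dy, f1z = w * dz;
    double f2x = -f1x, f2y = -f1y, f2z = -f1z;
    double s1 = std::sqrt(v1x * v1x + v1y * v1y + v1z * v1z);
    if (s1 > 0.0) {
      double fac = mt * (v0 - s1) / s1;
      f1x += fac * v1x; f1y += fac * v1y; f1z += fac * v1z;
    }
    double s2v = std::sqrt(v2x * v2x + v2y * v2y + v2z * v2z);
    if (s2v > 0.0) {
      double fac = mt * (v0 - s2v) / s2v;
      f2x += fac * v2x; f2y += fac * v2y; f2z += fac * v2z;
    }
    // forward Euler: positions advance with the pre-update velocities
    x1 += v1x * dt; y1 += v1y * dt; z1 += v1z * dt;
    x2 += v2x * dt; y2 += v2y * dt; z2 += v2z * dt;
    const double fm = dt / mass;
    v1x += f1x * fm; v1y += f1y * fm; v1z += f1z * fm;
    v2x += f2x * fm; v2y += f2y * fm; v2z += f2z * fm;
    if (sym_check_every > 0 && (s % sym_check_every) == 0) {
      // rotation by pi about y maps agent 1 onto agent 2
      double ax = std::fabs(-x1 - x2) / std::max(1.0, std::fabs(x2));
      double ay = std::fabs(y1 - y2) / std::max(1.0, std::fabs(y2));
      double az = std::fabs(-z1 - z2) / std::max(1.0, std::fabs(z2));
      double avx = std::fabs(-v1x - v2x) / std::max(1.0, std::fabs(v2x));
      double avy = std::fabs(v1y - v2y) / std::max(1.0, std::fabs(v2y));
      double avz = std::fabs(-v1z - v2z) / std::max(1.0, std::fabs(v2z));
      double m1 = std::max(std::max(ax, ay), az);
      double m2 = std::max(std::max(avx, avy), avz);
      if (m1 > max_asym) max_asym = m1;
      if (m2 > max_asym) max_asym = m2;
    }
  }
  if (s >= max_steps)
    stop("encounter step budget exceeded (%ld steps, %g s)", max_steps, max_time);
  double pf = mass * std::sqrt((v1x + v2x) * (v1x + v2x) +
                               (v1y + v2y) * (v1y + v2y) +
                               (v1z + v2z) * (v1z + v2z));
  NumericMatrix P(2, 3), V(2, 3);
  P(0, 0) = x1; P(0, 1) = y1; P(0, 2) = z1;
  P(1, 0) = x2; P(1, 1) = y2; P(1, 2) = z2;
  V(0, 0) = v1x; V(0, 1) = v1y; V(0, 2) = v1z;
  V(1, 0) = v2x; V(1, 1) = v2y; V(1, 2) = v2z;
  return List::create(
    _["delta_I"] = pf - p0, _["p_initial"] = p0, _["p_final"] = pf,
    _["steps"] = (double)s, _["elapsed"] = s * dt,
    _["closest_approach"] = std::sqrt(closest2),
    _["max_asymmetry"] = max_asym,
    _["positions"] = P, _["velocities"] = V);
}
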