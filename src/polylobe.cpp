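// Core numerics: site pair potentials, cell-list force/torque evaluation,
// rigid-body Langevin (BAOAB) propagation, and a separable exact Euclidean
// distance transform used by the pore-size analysis.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double SSLJ_CUT_FACTOR = 1.122462048309373; // 2^(1/6)
static const double LJ_CUT_FACTOR = 3.0;

// ---------------------------------------------------------------------------
// quaternion helpers (scalar-first convention: q = (w, x, y, z))

static inline void quat_mul(const double *a, const double *b, double *out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

// rotation matrix (body -> space), row-major
static inline void quat_to_mat(const double *q, double *R) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z);
  R[1] = 2 * (x * y - w * z);
  R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z);
  R[4] = 1 - 2 * (x * x + z * z);
  R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y);
  R[7] = 2 * (y * z + w * x);
  R[8] = 1 - 2 * (x * x + y * y);
}

static inline void quat_normalize(double *q) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  q[0] /= n; q[1] /= n; q[2] /= n; q[3] /= n;
}

// ---------------------------------------------------------------------------
// pair interaction: kinds 0 = seed, 1 = lobe.  Lobe-lobe pairs attract via a
// truncated-and-shifted LJ; seed-seed and seed-lobe pairs repel via the
// surface-shifted (WCA-like) LJ with delta = sigma_ij - 1.

struct PairOut { double energy; double f_over_r; }; // F_i = f_over_r * (x_i - x_j)

static inline bool pair_interact(double r, int ki, int kj, double di, double dj,
                                 double eps_sl, double eps_ll, bool wca_shift,
                                 PairOut &out) {
  double sigma = 0.5 * (di + dj);
  if (ki == 1 && kj == 1) { // attractive LJ
    double rc = LJ_CUT_FACTOR * sigma;
    if (r >= rc) return false;
    double s2 = (sigma * sigma) / (r * r);
    double s6 = s2 * s2 * s2;
    double s12 = s6 * s6;
    double sc6 = std::pow(1.0 / LJ_CUT_FACTOR, 6);
    double shift = 4.0 * eps_ll * (sc6 * sc6 - sc6);
    out.energy = 4.0 * eps_ll * (s12 - s6) - shift;
    out.f_over_r = 24.0 * eps_ll * (2.0 * s12 - s6) / (r * r);
    return true;
  }
  // SSLJ repulsion
  double delta = sigma - 1.0;
  double u = r - delta;
  if (u <= 1e-9 * sigma)
    stop("hard-core violation: site separation %f at or below surface shift %f",
         r, delta);
  if (u >= SSLJ_CUT_FACTOR * sigma) return false;
  double s2 = (sigma * sigma) / (u * u);
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  out.energy = 4.0 * eps_sl * (s12 - s6) + (wca_shift ? eps_sl : 0.0);
  out.f_over_r = 24.0 * eps_sl * (2.0 * s12 - s6) / (u * r);
  return true;
}

static inline double min_image(double d, double box) {
  d -= box * std::round(d / box);
  return d;
}

// maximum interaction range over all site pairs present
static double max_range(const NumericMatrix &diams, const IntegerVector &kinds) {
  double dmax_seed = 0, dmax_lobe = 0;
  int N = diams.nrow(), ns = diams.ncol();
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < ns; ++s) {
      double d = diams(i, s);
      if (kinds[s] == 0) { if (d > dmax_seed) dmax_seed = d; }
      else               { if (d > dmax_lobe) dmax_lobe = d; }
    }
  double r_lj = LJ_CUT_FACTOR * dmax_lobe;
  double smax = std::max(dmax_seed, 0.5 * (dmax_seed + dmax_lobe));
  double r_sslj = SSLJ_CUT_FACTOR * smax + (smax - 1.0);
  return std::max(r_lj, r_sslj);
}

// ---------------------------------------------------------------------------
// force/torque evaluation over all inter-particle site pairs

struct ForceWork {
  std::vector<double> sx, sy, sz;  // site positions (space frame)
  std::vector<double> ax, ay, az;  // site offsets from body center (space frame)
  std::vector<int> owner, skind;
  std::vector<double> sdiam;
};

static void build_sites(const NumericMatrix &centers, const NumericMatrix &quats,
                        const NumericMatrix &anchors, const NumericMatrix &diams,
                        const IntegerVector &kinds, ForceWork &w) {
  int N = centers.nrow(), ns = anchors.nrow();
  int M = N * ns;
  w.sx.resize(M); w.sy.resize(M); w.sz.resize(M);
  w.ax.resize(M); w.ay.resize(M); w.az.resize(M);
  w.owner.resize(M); w.skind.resize(M); w.sdiam.resize(M);
  double R[9], q[4];
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 4; ++k) q[k] = quats(i, k);
    quat_to_mat(q, R);
    for (int s = 0; s < ns; ++s) {
      double bx = anchors(s, 0), by = anchors(s, 1), bz = anchors(s, 2);
      double ox = R[0] * bx + R[1] * by + R[2] * bz;
      double oy = R[3] * bx + R[4] * by + R[5] * bz;
      double oz = R[6] * bx + R[7] * by + R[8] * bz;
      int m = i * ns + s;
      w.ax[m] = ox; w.ay[m] = oy; w.az[m] = oz;
      w.sx[m] = centers(i, 0) + ox;
      w.sy[m] = centers(i, 1) + oy;
      w.sz[m] = centers(i, 2) + oz;
      w.owner[m] = i; w.skind[m] = kinds[s]; w.sdiam[m] = diams(i, s);
    }
  }
}

static double accumulate_forces(const ForceWork &w, double box,
                                double eps_sl, double eps_ll, bool wca_shift,
                                bool use_cell_list,
                                double rmax,
                                std::vector<double> &fx, std::vector<double> &fy,
                                std::vector<double> &fz, std::vector<double> &tx,
                                std::vector<double> &ty, std::vector<double> &tz) {
  int M = (int)w.sx.size();
  double energy = 0.0;
  PairOut po;

  auto handle_pair = [&](int a, int b) {
    if (w.owner[a] == w.owner[b]) return; // rigid body: no intra-particle pairs
    double dx = min_image(w.sx[a] - w.sx[b], box);
    double dy = min_image(w.sy[a] - w.sy[b], box);
    double dz = min_image(w.sz[a] - w.sz[b], box);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rmax * rmax) return;
    double r = std::sqrt(r2);
    if (!pair_interact(r, w.skind[a], w.skind[b], w.sdiam[a], w.sdiam[b],
                       eps_sl, eps_ll, wca_shift, po)) return;
    energy += po.energy;
    double fxp = po.f_over_r * dx, fyp = po.f_over_r * dy, fzp = po.f_over_r * dz;
    int i = w.owner[a], j = w.owner[b];
    fx[i] += fxp; fy[i] += fyp; fz[i] += fzp;
    fx[j] -= fxp; fy[j] -= fyp; fz[j] -= fzp;
    tx[i] += w.ay[a] * fzp - w.az[a] * fyp;
    ty[i] += w.az[a] * fxp - w.ax[a] * fzp;
    tz[i] += w.ax[a] * fyp - w.ay[a] * fxp;
    tx[j] -= w.ay[b] * fzp - w.az[b] * fyp;
    ty[j] -= w.az[b] * fxp - w.ax[b] * fzp;
    tz[j] -= w.ax[b] * fyp - w.ay[b] * fxp;
  };

  int nc = (int)std::floor(box / rmax);
  if (!use_cell_list || nc < 3) {
    for (int a = 0; a < M; ++a)
      for (int b = a + 1; b < M; ++b) handle_pair(a, b);
    return energy;
  }

  double cell = box / nc;
  int ncells = nc * nc * nc;
  std::vector<int> head(ncells, -1), nxt(M, -1);
  for (int a = 0; a < M; ++a) {
    double x = w.sx[a] - box * std::floor(w.sx[a] / box);
    double y = w.sy[a] - box * std::floor(w.sy[a] / box);
    double z = w.sz[a] - box * std::floor(w.sz[a] / box);
    int ix = std::min((int)(x / cell), nc - 1);
    int iy = std::min((int)(y / cell), nc - 1);
    int iz = std::min((int)(z / cell), nc - 1);
    int c = (ix * nc + iy) * nc + iz;
    nxt[a] = head[c]; head[c] = a;
  }
  // half stencil: each unordered cell pair visited once
  static const int HALF[13][3] = {
    {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
    {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
    {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
    {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
  for (int ix = 0; ix < nc; ++ix)
    for (int iy = 0; iy < nc; ++iy)
      for (int iz = 0; iz < nc; ++iz) {
        int c = (ix * nc + iy) * nc + iz;
        if (head[c] == -1) continue;
        for (int a = head[c]; a != -1; a = nxt[a])
          for (int b = nxt[a]; b != -1; b = nxt[b]) handle_pair(a, b);
        for (int s = 0; s < 13; ++s) {
          int jx = (ix + HALF[s][0] + nc) % nc;
          int jy = (iy + HALF[s][1] + nc) % nc;
          int jz = (iz + HALF[s][2] + nc) % nc;
          int c2 = (jx * nc + jy) * nc + jz;
          if (c2 == c) continue; // nc == 3 wrap-around duplicate guard
          for (int a = head[c]; a != -1; a = nxt[a])
            for (int b = head[c2]; b != -1; b = nxt[b]) handle_pair(a, b);
        }
      }
  return energy;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix centers, NumericMatrix quats, NumericMatrix anchors,
                NumericMatrix diams, IntegerVector kinds, double box,
                double eps_sl, double eps_ll, bool wca_shift, bool use_cell_list) {
  int N = centers.nrow();
  ForceWork w;
  build_sites(centers, quats, anchors, diams, kinds, w);
  std::vector<double> fx(N, 0), fy(N, 0), fz(N, 0), tx(N, 0), ty(N, 0), tz(N, 0);
  double rmax = max_range(diams, kinds);
  double e = accumulate_forces(w, box, eps_sl, eps_ll, wca_shift, use_cell_list,
                               rmax, fx, fy, fz, tx, ty, tz);
  NumericMatrix F(N, 3), T(N, 3);
  for (int i = 0; i < N; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
    T(i, 0) = tx[i]; T(i, 1) = ty[i]; T(i, 2) = tz[i];
  }
  return List::create(_["force"] = F, _["torque"] = T, _["energy"] = e);
}

// ---------------------------------------------------------------------------
// free-rotor sub-rotation about body axis k for time t (exact under the
// single-axis Hamiltonian L_k^2 / 2 I_k); symmetric 3-2-1-2-3 composition
// gives a second-order, norm-preserving rigid rotation step.

static inline void axis_rotation(double *q, double *Lb, const double *inertia,
                                 int k, double t) {
  double omega = Lb[k] / inertia[k];
  double phi = omega * t;
  double h = 0.5 * phi, c = std::cos(h), s = std::sin(h);
  double dq[4] = {c, 0, 0, 0};
  dq[1 + k] = s;
  double qn[4];
  quat_mul(q, dq, qn);
  for (int m = 0; m < 4; ++m) q[m] = qn[m];
  // rotate body angular momentum about e_k by -phi
  int i = (k + 1) % 3, j = (k + 2) % 3;
  double cp = std::cos(phi), sp = std::sin(phi);
  double Li = cp * Lb[i] + sp * Lb[j];
  double Lj = -sp * Lb[i] + cp * Lb[j];
  Lb[i] = Li; Lb[j] = Lj;
}

static inline void free_rotor(double *q, double *Lb, const double *inertia, double t) {
  axis_rotation(q, Lb, inertia, 2, 0.5 * t);
  axis_rotation(q, Lb, inertia, 1, 0.5 * t);
  axis_rotation(q, Lb, inertia, 0, t);
  axis_rotation(q, Lb, inertia, 1, 0.5 * t);
  axis_rotation(q, Lb, inertia, 2, 0.5 * t);
  quat_normalize(q);
}

// ---------------------------------------------------------------------------
// Langevin (BAOAB) propagation of rigid bodies.  Angular momenta are kept in
// the body frame; the O-substep is the exact Ornstein-Uhlenbeck update, so the
// stationary velocity distribution is Maxwellian at T* and the gamma = 0,
// T_noise = 0 limit is plain velocity-Verlet with the symplectic free rotor.

// [[Rcpp::export]]
List cpp_run(NumericMatrix centers0, NumericMatrix quats0, NumericMatrix vels0,
             NumericMatrix angmom0, NumericMatrix anchors, NumericMatrix diams,
             IntegerVector kinds, double box, double mass, NumericVector inertia,
             double dt, double T_star, double gamma_t, double gamma_r,
             bool thermostat_on, int n_steps, double rng_seed,
             int write_every, int log_every,
             double eps_sl, double eps_ll, bool wca_shift, bool use_cell_list) {
  int N = centers0.nrow();
  NumericMatrix centers = clone(centers0), quats = clone(quats0),
    vels = clone(vels0), angmom = clone(angmom0);
  double I[3] = {inertia[0], inertia[1], inertia[2]};

  std::mt19937_64 rng((uint64_t)rng_seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  double c1t = 1.0, s1t = 0.0;
  double c1r[3] = {1, 1, 1}, s1r[3] = {0, 0, 0};
  if (thermostat_on) {
    c1t = std::exp(-gamma_t * dt / mass);
    s1t = std::sqrt((1.0 - c1t * c1t) * T_star / mass);
    for (int k = 0; k < 3; ++k) {
      c1r[k] = std::exp(-gamma_r * dt / I[k]);
      s1r[k] = std::sqrt((1.0 - c1r[k] * c1r[k]) * I[k] * T_star);
    }
  }

  double rmax = max_range(diams, kinds);
  ForceWork w;
  std::vector<double> fx(N), fy(N), fz(N), tx(N), ty(N), tz(N);

  auto eval_forces = [&]() -> double {
    std::fill(fx.begin(), fx.end(), 0.0); std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0); std::fill(tx.begin(), tx.end(), 0.0);
    std::fill(ty.begin(), ty.end(), 0.0); std::fill(tz.begin(), tz.end(), 0.0);
    build_sites(centers, quats, anchors, diams, kinds, w);
    return accumulate_forces(w, box, eps_sl, eps_ll, wca_shift, use_cell_list,
                             rmax, fx, fy, fz, tx, ty, tz);
  };

  double U = eval_forces();

  // body-frame torque for particle i
  double Rm[9], qv[4];
  auto body_torque = [&](int i, double *tb) {
    for (int k = 0; k < 4; ++k) qv[k] = quats(i, k);
    quat_to_mat(qv, Rm);
    // R^T * tau
    tb[0] = Rm[0] * tx[i] + Rm[3] * ty[i] + Rm[6] * tz[i];
    tb[1] = Rm[1] * tx[i] + Rm[4] * ty[i] + Rm[7] * tz[i];
    tb[2] = Rm[2] * tx[i] + Rm[5] * ty[i] + Rm[8] * tz[i];
  };

  int n_frames = (write_every > 0) ? n_steps / write_every : 0;
  int n_logs = (log_every > 0) ? n_steps / log_every : 0;
  List frames(n_frames);
  NumericMatrix scalars(n_logs, 5); // step, U, K_trans, K_rot, T_inst
  int fi = 0, li = 0;

  double half = 0.5 * dt;
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick (using forces/torques at current positions)
    for (int i = 0; i < N; ++i) {
      vels(i, 0) += half * fx[i] / mass;
      vels(i, 1) += half * fy[i] / mass;
      vels(i, 2) += half * fz[i] / mass;
      double tb[3]; body_torque(i, tb);
      angmom(i, 0) += half * tb[0];
      angmom(i, 1) += half * tb[1];
      angmom(i, 2) += half * tb[2];
    }
    // A: half drift
    for (int i = 0; i < N; ++i) {
      centers(i, 0) += half * vels(i, 0);
      centers(i, 1) += half * vels(i, 1);
      centers(i, 2) += half * vels(i, 2);
      double q[4] = {quats(i, 0), quats(i, 1), quats(i, 2), quats(i, 3)};
      double Lb[3] = {angmom(i, 0), angmom(i, 1), angmom(i, 2)};
      free_rotor(q, Lb, I, half);
      for (int k = 0; k < 4; ++k) quats(i, k) = q[k];
      for (int k = 0; k < 3; ++k) angmom(i, k) = Lb[k];
    }
    // O: exact Ornstein-Uhlenbeck on velocities / body angular momenta
    if (thermostat_on) {
      for (int i = 0; i < N; ++i) {
        for (int k = 0; k < 3; ++k)
          vels(i, k) = c1t * vels(i, k) + s1t * gauss(rng);
        for (int k = 0; k < 3; ++k)
          angmom(i, k) = c1r[k] * angmom(i, k) + s1r[k] * gauss(rng);
      }
    }
    // A: half drift
    for (int i = 0; i < N; ++i) {
      centers(i, 0) += half * vels(i, 0);
      centers(i, 1) += half * vels(i, 1);
      centers(i, 2) += half * vels(i, 2);
      double q[4] = {quats(i, 0), quats(i, 1), quats(i, 2), quats(i, 3)};
      double Lb[3] = {angmom(i, 0), angmom(i, 1), angmom(i, 2)};
      free_rotor(q, Lb, I, half);
      for (int k = 0; k < 4; ++k) quats(i, k) = q[k];
      for (int k = 0; k < 3; ++k) angmom(i, k) = Lb[k];
    }
    // wrap centers into [0, box)
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k)
        centers(i, k) -= box * std::floor(centers(i, k) / box);

    U = eval_forces();

    // B: half kick with new forces
    for (int i = 0; i < N; ++i) {
      vels(i, 0) += half * fx[i] / mass;
      vels(i, 1) += half * fy[i] / mass;
      vels(i, 2) += half * fz[i] / mass;
      double tb[3]; body_torque(i, tb);
      angmom(i, 0) += half * tb[0];
      angmom(i, 1) += half * tb[1];
      angmom(i, 2) += half * tb[2];
    }

    // stability guard: a body crossing a full interaction range in one step
    for (int i = 0; i < N; ++i) {
      double v2 = vels(i, 0) * vels(i, 0) + vels(i, 1) * vels(i, 1) +
        vels(i, 2) * vels(i, 2);
      if (std::sqrt(v2) * dt > 0.5 * rmax)
        stop("integration unstable at step %d: displacement per step exceeds "
             "half the interaction range (reduce dt)", step);
    }

    if (log_every > 0 && step % log_every == 0) {
      double kt = 0, kr = 0;
      for (int i = 0; i < N; ++i) {
        kt += 0.5 * mass * (vels(i, 0) * vels(i, 0) + vels(i, 1) * vels(i, 1) +
                            vels(i, 2) * vels(i, 2));
        for (int k = 0; k < 3; ++k)
          kr += 0.5 * angmom(i, k) * angmom(i, k) / I[k];
      }
      scalars(li, 0) = step;
      scalars(li, 1) = U;
      scalars(li, 2) = kt;
      scalars(li, 3) = kr;
      scalars(li, 4) = 2.0 * (kt + kr) / (6.0 * N); // 6 dof per rigid body
      ++li;
    }
    if (write_every > 0 && step % write_every == 0) {
      frames[fi++] = List::create(_["step"] = step,
                                  _["centers"] = clone(centers),
                                  _["quats"] = clone(quats));
    }
  }

  return List::create(_["centers"] = centers, _["quats"] = quats,
                      _["vels"] = vels, _["angmom"] = angmom,
                      _["frames"] = frames, _["scalars"] = scalars,
                      _["energy"] = U);
}

// ---------------------------------------------------------------------------
// exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1-D lower-envelope passes over a 3-D grid.  Input: logical array
// of "feature" voxels; output: squared distance (in voxel units) from every
// voxel to its nearest feature voxel.

static const double EDT_LARGE = 1e12; // > any attainable squared grid distance

static void edt_1d(std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t M = (size_t)nx * ny * nz;
  std::vector<double> g(M);
  for (size_t m = 0; m < M; ++m) g[m] = feature[m] ? 0.0 : EDT_LARGE;
  auto idx = [&](int i, int j, int k) { return (size_t)i + nx * ((size_t)j + (size_t)ny * k); };

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[idx(i, j, k)];
      edt_1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) g[idx(i, j, k)] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx(i, j, k)];
      edt_1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) g[idx(i, j, k)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[idx(i, j, k)];
      edt_1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) g[idx(i, j, k)] = d[k];
    }

  NumericVector out(M);
  for (size_t m = 0; m < M; ++m)
    out[m] = (g[m] >= EDT_LARGE) ? std::numeric_limits<double>::infinity() : g[m];
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// distance from every voxel center to the nearest site *surface*,
// max(0, min_s(|v - c_s| - r_s)); optionally under cubic minimum image.

// [[Rcpp::export]]
NumericVector cpp_site_distance_field(NumericVector vx, NumericVector vy,
                                      NumericVector vz, NumericMatrix sites,
                                      NumericVector radii, double box,
                                      bool periodic) {
  int M = vx.size(), S = sites.nrow();
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    double best = std::numeric_limits<double>::infinity();
    for (int s = 0; s < S; ++s) {
      double dx = vx[m] - sites(s, 0);
      double dy = vy[m] - sites(s, 1);
      double dz = vz[m] - sites(s, 2);
      if (periodic) {
        dx = min_image(dx, box); dy = min_image(dy, box); dz = min_image(dz, box);
      }
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[s];
      if (d < best) best = d;
    }
    out[m] = best > 0 ? best : 0.0;
  }
  return out;
}
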