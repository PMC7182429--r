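// Brownian-dynamics core for anisotropic capsomers.
//
// Pair interaction V = V_Mie * Va * Vtor with a WCA-style split of the Mie
// term: the repulsive core (r < sigma_ij, the potential minimum) is left
// unmodulated so that excluded volume never switches off at unfavourable
// orientations, while the attractive branch is multiplied by the angular
// and torsion factors.  A strict-product mode (modulation applied to the
// whole Mie term) is available for comparison.
//
// Reduced units: lengths in sigma, energies in eps0, time in sigma^2/D.
// Overdamped Euler updates; translational mobility D/kBT = 1/T_red,
// rotational diffusion Dr (default 3) with the orientation gradient
// projected on the tangent space of the unit sphere and renormalisation
// every step.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

struct PairParams {
  double m, n, eps, sigma, nu, alpha2, kt, rcut2, vshift;
  bool strict;
};

static inline double mie(double r, const PairParams& P) {
  double sr = P.sigma / r;
  double srn = std::pow(sr, P.n), srm = std::pow(sr, P.m);
  return P.eps * P.n / (P.m - P.n) * (srm - (P.m / P.n) * srn);
}
static inline double mie_d(double r, const PairParams& P) {
  double sr = P.sigma / r;
  double srn = std::pow(sr, P.n), srm = std::pow(sr, P.m);
  return P.eps * P.n / (P.m - P.n) *
         (-P.m * srm / r + (P.m / P.n) * P.n * srn / r);
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Full pair energy and analytic gradients.
// rv = x_j - x_i (minimum image).  gi, gj: dV/d u_i, dV/d u_j (unprojected);
// gr = dV/d rv.  Returns the energy.
static double pair_eval(const double* rv, const double* ui, const double* uj,
                        const PairParams& P,
                        double* gr, double* gi, double* gj, bool want_grad) {
  double r2 = dot3(rv, rv);
  for (int k = 0; k < 3; ++k) { gr[k] = 0; gi[k] = 0; gj[k] = 0; }
  if (r2 >= P.rcut2) return 0.0;
  double r = std::sqrt(r2);
  if (r < 1e-12) stop("coincident capsomers: pair distance is zero");
  double rhat[3] = { rv[0] / r, rv[1] / r, rv[2] / r };

  // distance split
  double vfull = mie(r, P), dfull = mie_d(r, P);
  double vrep, drep, vatt, datt;
  if (P.strict) {
    vrep = 0; drep = 0; vatt = vfull; datt = dfull;
  } else if (r < P.sigma) {
    vrep = vfull + P.eps; drep = dfull; vatt = -P.eps; datt = 0;
  } else {
    vrep = 0; drep = 0; vatt = vfull; datt = dfull;
  }
  vatt -= P.vshift;   // truncation shift on the attractive branch

  // angles
  double ci = dot3(ui, rhat);            // cos(theta_ij)
  double cj = -dot3(uj, rhat);           // cos(theta_ji)
  ci = std::max(-1.0, std::min(1.0, ci));
  cj = std::max(-1.0, std::min(1.0, cj));
  double thi = std::acos(ci), thj = std::acos(cj);
  double va = std::exp(-((thi - P.nu) * (thi - P.nu) +
                         (thj - P.nu) * (thj - P.nu)) / (2.0 * P.alpha2));

  // torsion: tangential components of the orientations
  double a[3], b[3];
  double uir = dot3(ui, rhat), ujr = dot3(uj, rhat);
  for (int k = 0; k < 3; ++k) {
    a[k] = ui[k] - uir * rhat[k];
    b[k] = uj[k] - ujr * rhat[k];
  }
  double na = std::sqrt(dot3(a, a)), nb = std::sqrt(dot3(b, b));
  double cxi = 1.0, vtor = 1.0;
  bool tors_ok = (na > 1e-9 && nb > 1e-9);
  if (tors_ok) {
    cxi = dot3(a, b) / (na * nb);
    cxi = std::max(-1.0, std::min(1.0, cxi));
    vtor = std::exp(-P.kt * (1.0 - cxi) * (1.0 - cxi));
  }

  double M = va * vtor;
  double V = vrep + vatt * M;
  if (!want_grad) return V;

  // ---- gradients -------------------------------------------------------
  // radial part
  double drad = drep + datt * M;
  for (int k = 0; k < 3; ++k) gr[k] += drad * rhat[k];

  // angular part: dV/dthi = vatt * vtor * dva/dthi
  double dV_dthi = vatt * vtor * va * (-(thi - P.nu) / P.alpha2);
  double dV_dthj = vatt * vtor * va * (-(thj - P.nu) / P.alpha2);
  // dthi/dci = -1/sin(thi); with p_i = a (tangential part of u_i),
  // dci/drv = a / r, |a| = sin(thi) -> bounded combination via unit a.
  double si = std::sqrt(std::max(1.0 - ci * ci, 1e-14));
  double sj = std::sqrt(std::max(1.0 - cj * cj, 1e-14));
  // dci/dui = rhat; dci/drv = a/r.  dcj/duj = -rhat; dcj/drv = -b/r.
  for (int k = 0; k < 3; ++k) {
    gi[k] += dV_dthi * (-1.0 / si) * rhat[k];
    gj[k] += dV_dthj * (+1.0 / sj) * rhat[k];
    gr[k] += dV_dthi * (-1.0 / si) * a[k] / r
           + dV_dthj * (-1.0 / sj) * (-b[k] / r);
  }

  // torsion part
  if (tors_ok) {
    double dV_dc = vatt * va * vtor * (2.0 * P.kt * (1.0 - cxi));
    double ga[3], gb[3];
    for (int k = 0; k < 3; ++k) {
      ga[k] = (b[k] / nb - cxi * a[k] / na) / na;
      gb[k] = (a[k] / na - cxi * b[k] / nb) / nb;
    }
    double gar = dot3(ga, rhat), gbr = dot3(gb, rhat);
    // d a/d ui = I - rhat rhat^T ; d b/d uj likewise
    for (int k = 0; k < 3; ++k) {
      gi[k] += dV_dc * (ga[k] - gar * rhat[k]);
      gj[k] += dV_dc * (gb[k] - gbr * rhat[k]);
    }
    // through rhat:  ds/drhat = -(ui.rhat) ga - (ga.rhat) ui
    //                           -(uj.rhat) gb - (gb.rhat) uj
    double drh[3];
    for (int k = 0; k < 3; ++k)
      drh[k] = -uir * ga[k] - gar * ui[k] - ujr * gb[k] - gbr * uj[k];
    double drr = dot3(drh, rhat);
    for (int k = 0; k < 3; ++k)
      gr[k] += dV_dc * (drh[k] - drr * rhat[k]) / r;
  }
  return V;
}

static PairParams make_params(List pp, double cutoff, bool strict) {
  PairParams P;
  P.m = as<double>(pp["m"]); P.n = as<double>(pp["n"]);
  P.eps = 1.0;                      // energies in units of eps0
  P.sigma = 1.0;                    // lengths in units of sigma
  P.nu = as<double>(pp["nu"]);
  double alpha = as<double>(pp["alpha"]);
  P.alpha2 = alpha * alpha;
  P.kt = as<double>(pp["kt"]);
  P.rcut2 = cutoff * cutoff;
  P.strict = strict;
  P.vshift = mie(cutoff, P);        // shift the attractive branch to 0 at rc
  return P;
}

// [[Rcpp::export(name = ".cpp_pair_energy")]]
double cpp_pair_energy(NumericVector rvec, NumericVector oi, NumericVector oj,
                       List pp, double cutoff, bool strict) {
  PairParams P = make_params(pp, cutoff, strict);
  double gr[3], gi[3], gj[3];
  return pair_eval(&rvec[0], &oi[0], &oj[0], P, gr, gi, gj, false);
}

// [[Rcpp::export(name = ".cpp_pair_gradients")]]
List cpp_pair_gradients(NumericVector rvec, NumericVector oi,
                        NumericVector oj, List pp, double cutoff,
                        bool strict) {
  PairParams P = make_params(pp, cutoff, strict);
  double gr[3], gi[3], gj[3];
  double V = pair_eval(&rvec[0], &oi[0], &oj[0], P, gr, gi, gj, true);
  return List::create(_["energy"] = V,
                      _["dV_drvec"] = NumericVector(gr, gr + 3),
                      _["dV_doi"] = NumericVector(gi, gi + 3),
                      _["dV_doj"] = NumericVector(gj, gj + 3));
}

static inline void min_image(double* d, double L) {
  for (int k = 0; k < 3; ++k) {
    d[k] -= L * std::round(d[k] / L);
  }
}

// forces, orientation gradients (projected), total energy; O(N^2) pairs
static double all_forces(const std::vector<double>& x,
                         const std::vector<double>& u,
                         double L, const PairParams& P, double fmax,
                         std::vector<double>& F, std::vector<double>& T,
                         int* nclamp) {
  int N = (int)x.size() / 3;
  std::fill(F.begin(), F.end(), 0.0);
  std::fill(T.begin(), T.end(), 0.0);
  double E = 0.0;
  double gr[3], gi[3], gj[3], rv[3];
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      for (int k = 0; k < 3; ++k) rv[k] = x[3 * j + k] - x[3 * i + k];
      if (L > 0) min_image(rv, L);
      double r2 = dot3(rv, rv);
      if (r2 >= P.rcut2) continue;
      E += pair_eval(rv, &u[3 * i], &u[3 * j], P, gr, gi, gj, true);
      // clamp hard-core forces for overlapping capsomers
      double g2 = dot3(gr, gr);
      if (g2 > fmax * fmax) {
        double s = fmax / std::sqrt(g2);
        for (int k = 0; k < 3; ++k) gr[k] *= s;
        if (nclamp) ++(*nclamp);
      }
      for (int k = 0; k < 3; ++k) {
        F[3 * i + k] += gr[k];        // F_i = -dV/dx_i = +dV/drv
        F[3 * j + k] -= gr[k];
        T[3 * i + k] -= gi[k];        // orientation force = -dV/dOmega
        T[3 * j + k] -= gj[k];
      }
    }
  }
  // project orientation gradients on the tangent space
  for (int i = 0; i < N; ++i) {
    double d = dot3(&T[3 * i], &u[3 * i]);
    for (int k = 0; k < 3; ++k) T[3 * i + k] -= d * u[3 * i + k];
  }
  return E;
}

// [[Rcpp::export(name = ".cpp_forces")]]
List cpp_forces(NumericMatrix pos, NumericMatrix ori, double box, List pp,
                double cutoff, bool strict, double fmax) {
  int N = pos.nrow();
  PairParams P = make_params(pp, cutoff, strict);
  std::vector<double> x(3 * N), u(3 * N), F(3 * N), T(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { x[3*i+k] = pos(i, k); u[3*i+k] = ori(i, k); }
  int nclamp = 0;
  double E = all_forces(x, u, box, P, fmax, F, T, &nclamp);
  NumericMatrix Fm(N, 3), Tm(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { Fm(i, k) = F[3*i+k]; Tm(i, k) = T[3*i+k]; }
  return List::create(_["force"] = Fm, _["torque"] = Tm, _["energy"] = E,
                      _["n_clamped"] = nclamp);
}

// [[Rcpp::export(name = ".cpp_bd_run")]]
List cpp_bd_run(NumericMatrix pos, NumericMatrix ori, double box, List pp,
                double cutoff, bool strict, int n_steps, double dt,
                double T_red, double Dr, int seed, int thin, double fmax) {
  int N = pos.nrow();
  PairParams P = make_params(pp, cutoff, strict);
  std::vector<double> x(3 * N), u(3 * N), F(3 * N), T(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { x[3*i+k] = pos(i, k); u[3*i+k] = ori(i, k); }

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // mobility D/kBT = 1/T_red; in the zero-temperature relaxation mode the
  // update is plain gradient descent with unit mobility and no noise
  bool thermal = T_red > 0;
  double mob = thermal ? 1.0 / T_red : 1.0;
  double mob_r = thermal ? Dr / T_red : 1.0;
  double amp_t = thermal ? std::sqrt(2.0 * dt) : 0.0;       // D = 1
  double amp_r = thermal ? std::sqrt(2.0 * Dr * dt) : 0.0;

  int nframes = (thin > 0) ? (n_steps / thin) : 0;
  NumericMatrix traj_x(nframes * N, 3), traj_u(nframes * N, 3);
  NumericVector traj_step(nframes), energies(nframes);
  int frame = 0, nclamp = 0;
  double max_disp = 0.0;

  for (int s = 1; s <= n_steps; ++s) {
    all_forces(x, u, box, P, fmax, F, T, &nclamp);
    for (int i = 0; i < N; ++i) {
      double dx[3];
      for (int k = 0; k < 3; ++k) {
        dx[k] = mob * F[3*i+k] * dt + amp_t * gauss(rng);
        x[3*i+k] += dx[k];
      }
      double dd = std::sqrt(dot3(dx, dx));
      if (dd > max_disp) max_disp = dd;
      if (box > 0) {
        for (int k = 0; k < 3; ++k) {
          x[3*i+k] -= box * std::floor(x[3*i+k] / box);
        }
      }
      // rotational update on the tangent space, then renormalise
      double du[3];
      for (int k = 0; k < 3; ++k)
        du[k] = mob_r * T[3*i+k] * dt + amp_r * gauss(rng);
      double d = dot3(du, &u[3*i]);
      for (int k = 0; k < 3; ++k) u[3*i+k] += du[k] - d * u[3*i+k];
      double nrm = std::sqrt(dot3(&u[3*i], &u[3*i]));
      for (int k = 0; k < 3; ++k) u[3*i+k] /= nrm;
    }
    if (thin > 0 && s % thin == 0 && frame < nframes) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < 3; ++k) {
          traj_x(frame * N + i, k) = x[3*i+k];
          traj_u(frame * N + i, k) = u[3*i+k];
        }
      traj_step[frame] = s;
      energies[frame] = all_forces(x, u, box, P, fmax, F, T, nullptr);
      ++frame;
    }
  }
  NumericMatrix X(N, 3), U(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { X(i, k) = x[3*i+k]; U(i, k) = u[3*i+k]; }
  return List::create(_["positions"] = X, _["orientations"] = U,
                      _["traj_positions"] = traj_x,
                      _["traj_orientations"] = traj_u,
                      _["traj_step"] = traj_step,
                      _["traj_energy"] = energies,
                      _["n_frames"] = frame,
                      _["n_clamped"] = nclamp,
                      _["max_displacement"] = max_disp);
}
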