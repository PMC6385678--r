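// Brownian-dynamics toy model of bimolecular association: a mobile patchy
// sphere (ligand) diffusing around a fixed patchy sphere (receptor, patch
// axis +z) inside a reflecting spherical shell.  Overdamped Langevin
// (Euler-Maruyama) translation + rotational diffusion with torque drift.
// Reduced units: kT = 1, lengths "Angstrom-like", times "ps-like".

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include "rng.h"
using namespace Rcpp;

struct TP {
  double Rrec, Rlig, eps, prec, plig, wenc, Dt, Dr, dt, kT, Rout, rcut, krep;
  double absorb;       // absorbing radius (0 = no absorbing boundary)
  double Rc;           // contact distance R_rec + R_lig
  double a[2][3];      // anchor points, ligand body frame
  double aref[2][3];   // anchor points of the bound reference pose, lab frame
};

static TP parse_params(const List& pl) {
  TP P;
  P.Rrec = as<double>(pl["R_rec"]);
  P.Rlig = as<double>(pl["R_lig"]);
  P.eps  = as<double>(pl["eps"]);
  P.prec = as<double>(pl["p_rec"]);
  P.plig = as<double>(pl["p_lig"]);
  P.wenc = as<double>(pl["w_enc"]);
  P.Dt   = as<double>(pl["D_t"]);
  P.Dr   = as<double>(pl["D_r"]);
  P.dt   = as<double>(pl["dt"]);
  P.kT   = as<double>(pl["kT"]);
  P.Rout = as<double>(pl["R_out"]);
  P.rcut = as<double>(pl["r_cut"]);
  P.krep = as<double>(pl["k_rep"]);
  P.absorb = pl.containsElementNamed("absorb_radius")
    ? as<double>(pl["absorb_radius"]) : 0.0;
  P.Rc   = P.Rrec + P.Rlig;
  NumericMatrix A = pl["anchor_points"];
  for (int i = 0; i < 2; ++i)
    for (int k = 0; k < 3; ++k) P.a[i][k] = A(i, k);
  // Bound reference pose: ligand centre at (0,0,Rc), patch axis rotated to
  // point back at the receptor (180 degrees about x: (x,y,z)->(x,-y,-z)).
  for (int i = 0; i < 2; ++i) {
    P.aref[i][0] = P.a[i][0];
    P.aref[i][1] = -P.a[i][1];
    P.aref[i][2] = P.Rc - P.a[i][2];
  }
  return P;
}

// rotate v by unit quaternion q = (w,x,y,z): v' = v + 2 u x (u x v + w v)
static inline void qrot(const double* q, const double* v, double* out) {
  double ux = q[1], uy = q[2], uz = q[3], w = q[0];
  double t0 = uy * v[2] - uz * v[1] + w * v[0];
  double t1 = uz * v[0] - ux * v[2] + w * v[1];
  double t2 = ux * v[1] - uy * v[0] + w * v[2];
  out[0] = v[0] + 2.0 * (uy * t2 - uz * t1);
  out[1] = v[1] + 2.0 * (uz * t0 - ux * t2);
  out[2] = v[2] + 2.0 * (ux * t1 - uy * t0);
}

static inline void qmul(const double* a, const double* b, double* out) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

// apply rotation vector w (axis * angle) to quaternion q in place
static inline void rotvec_apply(const double* w, double* q) {
  double a2 = w[0]*w[0] + w[1]*w[1] + w[2]*w[2];
  double dq[4];
  if (a2 < 1e-24) {
    dq[0] = 1.0; dq[1] = 0.5 * w[0]; dq[2] = 0.5 * w[1]; dq[3] = 0.5 * w[2];
  } else {
    double a = std::sqrt(a2), h = 0.5 * a, s = std::sin(h) / a;
    dq[0] = std::cos(h); dq[1] = s * w[0]; dq[2] = s * w[1]; dq[3] = s * w[2];
  }
  double out[4];
  qmul(dq, q, out);
  double n = std::sqrt(out[0]*out[0] + out[1]*out[1] + out[2]*out[2] + out[3]*out[3]);
  for (int k = 0; k < 4; ++k) q[k] = out[k] / n;
}

// Potential U(r, theta_r, theta_l) and (optionally) force / torque.
//   U = U_rep(r) - eps * f(r) * [ g(cr)^p_rec g(cl)^p_lig + w_enc h(cr,cl) ]
// with g(x) = max(x,0), h = g(cr)^2 (1 - cl^2) (broad low-alignment
// shoulder: right location, free ligand orientation -> encounter basin),
// f a C1 switch equal to 1 at contact and 0 at r_cut, and U_rep a soft
// quadratic core below contact.  F and T may be NULL.
static double toy_force(const TP& P, const double* p, const double* q,
                        double* F, double* T) {
  double r2 = p[0]*p[0] + p[1]*p[1] + p[2]*p[2];
  double r = std::sqrt(r2);
  if (F) { F[0] = F[1] = F[2] = 0.0; }
  if (T) { T[0] = T[1] = T[2] = 0.0; }
  if (r < 1e-8) {
    // ligand centre exactly on the receptor centre: flat top of the soft
    // core; no defined direction, zero force
    return P.krep;
  }
  double rh[3] = { p[0]/r, p[1]/r, p[2]/r };
  double U = 0.0, dUrep = 0.0;
  if (r < P.Rc) {
    double x = 1.0 - r / P.Rc;
    U += P.krep * x * x;
    dUrep = -2.0 * P.krep * x / P.Rc;
  }
  if (r >= P.rcut || P.eps == 0.0) {
    if (F) for (int k = 0; k < 3; ++k) F[k] = -dUrep * rh[k];
    return U;
  }
  double f, df;
  if (r <= P.Rc) {
    f = 1.0; df = 0.0;
  } else {
    double den = P.rcut - P.Rc;
    double s = (r - P.Rc) / den;
    f = 1.0 - s * s * (3.0 - 2.0 * s);
    df = -6.0 * s * (1.0 - s) / den;
  }
  double ez[3] = {0.0, 0.0, 1.0};
  double az[3];
  qrot(q, ez, az);                       // ligand patch axis, lab frame
  double cr = rh[2];                     // receptor patch vs ligand direction
  double cl = -(az[0]*rh[0] + az[1]*rh[1] + az[2]*rh[2]);
  double gr = cr > 0.0 ? cr : 0.0;
  double gl = cl > 0.0 ? cl : 0.0;
  double grp = std::pow(gr, P.prec), glp = std::pow(gl, P.plig);
  double h = gr * gr * (1.0 - cl * cl);
  double A = grp * glp + P.wenc * h;
  U += -P.eps * f * A;
  if (!F && !T) return U;
  double A_cr = (cr > 0.0)
    ? P.prec * std::pow(gr, P.prec - 1.0) * glp + P.wenc * 2.0 * gr * (1.0 - cl * cl)
    : 0.0;
  double A_cl = ((cl > 0.0) ? P.plig * std::pow(gl, P.plig - 1.0) * grp : 0.0)
    - P.wenc * gr * gr * 2.0 * cl;
  if (F) {
    for (int k = 0; k < 3; ++k) {
      double ezk = (k == 2) ? 1.0 : 0.0;
      double gcr = (ezk - cr * rh[k]) / r;
      double gcl = -(az[k] + cl * rh[k]) / r;
      double gradU = dUrep * rh[k]
        - P.eps * (df * A * rh[k] + f * (A_cr * gcr + A_cl * gcl));
      F[k] = -gradU;
    }
  }
  if (T) {
    double cx = az[1]*rh[2] - az[2]*rh[1];
    double cy = az[2]*rh[0] - az[0]*rh[2];
    double cz = az[0]*rh[1] - az[1]*rh[0];
    double c = -P.eps * f * A_cl;       // torque = -a x dU/da
    T[0] = c * cx; T[1] = c * cy; T[2] = c * cz;
  }
  return U;
}

// one Euler-Maruyama step; returns false on step divergence
static bool toy_step(const TP& P, double* p, double* q, WepRng& rng) {
  double F[3], T[3];
  double r2 = p[0]*p[0] + p[1]*p[1] + p[2]*p[2];
  bool near = r2 < P.rcut * P.rcut;
  if (near) {
    toy_force(P, p, q, F, T);
  } else {
    F[0] = F[1] = F[2] = 0.0;
    T[0] = T[1] = T[2] = 0.0;
  }
  double sdt = std::sqrt(2.0 * P.Dt * P.dt);
  double dx[3], n2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    dx[k] = (P.Dt / P.kT) * F[k] * P.dt + sdt * rng.norm();
    n2 += dx[k] * dx[k];
  }
  if (n2 > P.Rrec * P.Rrec) return false;
  for (int k = 0; k < 3; ++k) p[k] += dx[k];
  double r = std::sqrt(p[0]*p[0] + p[1]*p[1] + p[2]*p[2]);
  if (r > P.Rout) {
    double sc = (2.0 * P.Rout - r) / r;  // radial reflection
    for (int k = 0; k < 3; ++k) p[k] *= sc;
  }
  double srdt = std::sqrt(2.0 * P.Dr * P.dt);
  double w[3];
  for (int k = 0; k < 3; ++k)
    w[k] = (P.Dr / P.kT) * T[k] * P.dt + srdt * rng.norm();
  rotvec_apply(w, q);
  return true;
}

// progress coordinate: out[0] = min separation (surface-surface, clamped at
// 0), out[1] = binding RMSD of the two anchor points vs the bound reference
static void toy_pc(const TP& P, const double* p, const double* q, double* out) {
  double r = std::sqrt(p[0]*p[0] + p[1]*p[1] + p[2]*p[2]);
  double ms = r - P.Rc;
  out[0] = ms > 0.0 ? ms : 0.0;
  double s2 = 0.0;
  for (int i = 0; i < 2; ++i) {
    double lab[3];
    qrot(q, P.a[i], lab);
    for (int k = 0; k < 3; ++k) {
      double d = p[k] + lab[k] - P.aref[i][k];
      s2 += d * d;
    }
  }
  out[1] = std::sqrt(s2 / 2.0);
}

// [[Rcpp::export]]
double cpp_toy_energy(NumericVector state, List params) {
  TP P = parse_params(params);
  double p[3] = { state[0], state[1], state[2] };
  double q[4] = { state[3], state[4], state[5], state[6] };
  return toy_force(P, p, q, (double*)0, (double*)0);
}

// [[Rcpp::export]]
NumericMatrix cpp_toy_propagate(NumericMatrix states, int n_steps, List params,
                                double seed, IntegerVector ids, int iteration) {
  TP P = parse_params(params);
  int n = states.nrow();
  NumericMatrix out(n, 7);
  for (int i = 0; i < n; ++i) {
    double p[3] = { states(i,0), states(i,1), states(i,2) };
    double q[4] = { states(i,3), states(i,4), states(i,5), states(i,6) };
    WepRng rng(seed, ids[i], iteration);
    bool absorbed = P.absorb > 0.0 &&
      p[0]*p[0] + p[1]*p[1] + p[2]*p[2] <= P.absorb * P.absorb;
    for (int s = 0; s < n_steps && !absorbed; ++s) {
      if (!toy_step(P, p, q, rng))
        stop("propagation step exceeded R_rec for walker id %d: reduce dt",
             ids[i]);
      if (P.absorb > 0.0 &&
          p[0]*p[0] + p[1]*p[1] + p[2]*p[2] <= P.absorb * P.absorb)
        absorbed = true;   // absorbing boundary: walker stays put
    }
    for (int k = 0; k < 3; ++k) out(i, k) = p[k];
    for (int k = 0; k < 4; ++k) out(i, 3 + k) = q[k];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_toy_pcoord(NumericMatrix states, List params) {
  TP P = parse_params(params);
  int n = states.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double p[3] = { states(i,0), states(i,1), states(i,2) };
    double q[4] = { states(i,3), states(i,4), states(i,5), states(i,6) };
    double pc[2];
    toy_pc(P, p, q, pc);
    out(i, 0) = pc[0];
    out(i, 1) = pc[1];
  }
  return out;
}

static inline bool stop_hit(const TP& P, const double* p, const double* q,
                            double stop_rmsd, double stop_sep,
                            double stop_radius, double* pc) {
  toy_pc(P, p, q, pc);
  if (stop_radius > 0.0) {
    double r = std::sqrt(p[0]*p[0] + p[1]*p[1] + p[2]*p[2]);
    return r <= stop_radius;
  }
  if (stop_rmsd >= 0.0)
    return pc[1] <= stop_rmsd && pc[0] <= stop_sep;
  return false;
}

// First-passage propagation without trajectory storage.  The stopping
// condition is checked every check_every steps (tau-resolution detection,
// matching the WE analysis convention); check_every = 1 gives per-step
// detection for oracle use.
// [[Rcpp::export]]
List cpp_toy_fpt(NumericVector state, List params, double seed, int id,
                 int iteration, double max_steps, int check_every,
                 double stop_rmsd, double stop_sep, double stop_radius) {
  TP P = parse_params(params);
  double p[3] = { state[0], state[1], state[2] };
  double q[4] = { state[3], state[4], state[5], state[6] };
  double pc[2];
  WepRng rng(seed, id, iteration);
  if (stop_hit(P, p, q, stop_rmsd, stop_sep, stop_radius, pc))
    return List::create(_["n_steps"] = 0.0, _["hit"] = true);
  double nstep = 0.0;
  while (nstep < max_steps) {
    for (int s = 0; s < check_every; ++s) {
      if (!toy_step(P, p, q, rng))
        stop("propagation step exceeded R_rec: reduce dt");
    }
    nstep += check_every;
    if (stop_hit(P, p, q, stop_rmsd, stop_sep, stop_radius, pc))
      return List::create(_["n_steps"] = nstep, _["hit"] = true);
  }
  return List::create(_["n_steps"] = nstep, _["hit"] = false);
}

// Recorded trajectory: every record_every steps append
// [min_sep, binding_rmsd, r, ux, uy, uz] (u = receptor-to-ligand unit
// vector).  Stops at the first record satisfying the stop condition
// (tau-resolution detection).  stop_rmsd < 0 and stop_radius <= 0 disables
// stopping.
// [[Rcpp::export]]
List cpp_toy_path(NumericVector state, List params, double seed, int id,
                  int iteration, double max_steps, int record_every,
                  double stop_rmsd, double stop_sep, double stop_radius) {
  TP P = parse_params(params);
  double p[3] = { state[0], state[1], state[2] };
  double q[4] = { state[3], state[4], state[5], state[6] };
  WepRng rng(seed, id, iteration);
  int max_rec = (int)(max_steps / record_every) + 1;
  NumericMatrix rec(max_rec, 6);
  int nrec = 0;
  double nstep = 0.0;
  bool hit = false;
  double pc[2];
  while (nstep < max_steps) {
    for (int s = 0; s < record_every; ++s) {
      if (!toy_step(P, p, q, rng))
        stop("propagation step exceeded R_rec: reduce dt");
    }
    nstep += record_every;
    double r = std::sqrt(p[0]*p[0] + p[1]*p[1] + p[2]*p[2]);
    toy_pc(P, p, q, pc);
    rec(nrec, 0) = pc[0];
    rec(nrec, 1) = pc[1];
    rec(nrec, 2) = r;
    rec(nrec, 3) = p[0] / r;
    rec(nrec, 4) = p[1] / r;
    rec(nrec, 5) = p[2] / r;
    nrec++;
    bool stop_now = false;
    if (stop_radius > 0.0) stop_now = r <= stop_radius;
    else if (stop_rmsd >= 0.0) stop_now = pc[1] <= stop_rmsd && pc[0] <= stop_sep;
    if (stop_now) { hit = true; break; }
  }
  NumericVector fin(7);
  for (int k = 0; k < 3; ++k) fin[k] = p[k];
  for (int k = 0; k < 4; ++k) fin[3 + k] = q[k];
  return List::create(_["records"] = rec(Range(0, nrec > 0 ? nrec - 1 : 0), _),
                      _["n_records"] = nrec,
                      _["n_steps"] = nstep,
                      _["hit"] = hit,
                      _["state"] = fin);
}
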