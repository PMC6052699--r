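// Semi-implicit (symplectic) Euler integrator for the two-tier mass-spring
// skin lattice. Hookean springs with axial viscous damping; kinematic
// (invmass == 0) vertices never move; weld pairs and rigid shape-matching
// chains are enforced by projection after each position update.
#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Best-fit rigid transform (Kabsch) of a stored reference shape onto the
// current chain positions, then project the chain onto that fit.
static void project_rigid(double *px, double *py, double *pz,
                          double *vx, double *vy, double *vz,
                          const std::vector<int> &idx, const arma::mat &ref,
                          const std::vector<double> &prev_x,
                          const std::vector<double> &prev_y,
                          const std::vector<double> &prev_z, double dt) {
  const size_t n = idx.size();
  if (n < 2) return;
  arma::mat P(n, 3);
  for (size_t r = 0; r < n; ++r) {
    P(r, 0) = px[idx[r]];
    P(r, 1) = py[idx[r]];
    P(r, 2) = pz[idx[r]];
  }
  arma::mat Q = ref;
  arma::rowvec cP = arma::mean(P, 0), cQ = arma::mean(Q, 0);
  P.each_row() -= cP;
  Q.each_row() -= cQ;
  arma::mat H = Q.t() * P;  // 3x3 covariance, ref -> current
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) return;  // degenerate: leave positions alone
  arma::mat R = V * U.t();
  if (arma::det(R) < 0) {  // reflection guard
    V.col(2) *= -1.0;
    R = V * U.t();
  }
  for (size_t r = 0; r < n; ++r) {
    arma::rowvec p = cP + (R * Q.row(r).t()).t();
    const int i = idx[r];
    px[i] = p[0]; py[i] = p[1]; pz[i] = p[2];
    vx[i] = (p[0] - prev_x[r]) / dt;
    vy[i] = (p[1] - prev_y[r]) / dt;
    vz[i] = (p[2] - prev_z[r]) / dt;
  }
}

// [[Rcpp::export]]
List integrate_system(NumericMatrix pos_in, NumericMatrix vel_in,
                      NumericVector mass, NumericVector invmass,
                      IntegerVector si, IntegerVector sj,
                      NumericVector rest, NumericVector stiff,
                      NumericVector damp, double dt, NumericVector gravity,
                      int max_steps, double vtol, double dtol,
                      List rigid_idx, List rigid_ref,
                      IntegerVector weld_free, IntegerVector weld_anchor,
                      double drag, double speed_ceiling,
                      bool check_convergence, bool record_energy) {
  const int n = pos_in.nrow();
  const int m = si.size();
  std::vector<double> px(n), py(n), pz(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos_in(i, 0); py[i] = pos_in(i, 1); pz[i] = pos_in(i, 2);
    vx[i] = vel_in(i, 0); vy[i] = vel_in(i, 1); vz[i] = vel_in(i, 2);
  }
  std::vector<int> ia(m), ib(m);
  for (int e = 0; e < m; ++e) { ia[e] = si[e] - 1; ib[e] = sj[e] - 1; }
  const double gx = gravity[0], gy = gravity[1], gz = gravity[2];
  const double *inv = invmass.begin();
  const double *ms = mass.begin();
  const double *rl = rest.begin(), *kk = stiff.begin(), *cc = damp.begin();

  const int ng = rigid_idx.size();
  std::vector<std::vector<int> > gidx(ng);
  std::vector<arma::mat> gref(ng);
  for (int k = 0; k < ng; ++k) {
    IntegerVector iv = rigid_idx[k];
    gidx[k].resize(iv.size());
    for (int r = 0; r < iv.size(); ++r) gidx[k][r] = iv[r] - 1;  // 1-based
    gref[k] = as<arma::mat>(rigid_ref[k]);
  }
  const int nw = weld_free.size();
  std::vector<int> wf(nw), wa(nw);
  for (int w = 0; w < nw; ++w) { wf[w] = weld_free[w] - 1; wa[w] = weld_anchor[w] - 1; }

  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<double> qx(n), qy(n), qz(n);  // step-start positions
  std::vector<double> energies;
  if (record_energy) energies.reserve(max_steps < 100000 ? max_steps : 100000);

  int steps = 0;
  bool converged = false, diverged = false;
  double max_speed = 0.0, max_disp = 0.0;
  // the tolerances must hold over a streak of steps long enough to span a
  // half period of the stiffest surviving oscillation: a short slow window
  // can be an oscillation turning point, not equilibrium
  int streak = 0;
  const int streak_needed = 60;

  for (int it = 0; it < max_steps; ++it) {
    ++steps;
    qx = px; qy = py; qz = pz;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int e = 0; e < m; ++e) {
      const int a = ia[e], b = ib[e];
      const double dx = px[b] - px[a], dy = py[b] - py[a], dz = pz[b] - pz[a];
      const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len < 1e-12) continue;  // coincident endpoints: no defined axis
      const double ux = dx / len, uy = dy / len, uz = dz / len;
      const double vrel = (vx[b] - vx[a]) * ux + (vy[b] - vy[a]) * uy +
                          (vz[b] - vz[a]) * uz;
      const double f = kk[e] * (len - rl[e]) + cc[e] * vrel;
      fx[a] += f * ux; fy[a] += f * uy; fz[a] += f * uz;
      fx[b] -= f * ux; fy[b] -= f * uy; fz[b] -= f * uz;
    }
    const double keep = 1.0 - dt * drag;  // global viscous drag: damps
    // transverse/bending modes the axial spring damping cannot see;
    // vanishes at rest, so equilibria are unchanged
    for (int i = 0; i < n; ++i) {
      if (inv[i] > 0.0) {
        vx[i] = vx[i] * keep + dt * (fx[i] * inv[i] + gx);
        vy[i] = vy[i] * keep + dt * (fy[i] * inv[i] + gy);
        vz[i] = vz[i] * keep + dt * (fz[i] * inv[i] + gz);
        // flush-to-zero: exponential drag decay otherwise drives settled
        // velocities subnormal, stalling the FPU
        if (std::fabs(vx[i]) < 1e-14) vx[i] = 0.0;
        if (std::fabs(vy[i]) < 1e-14) vy[i] = 0.0;
        if (std::fabs(vz[i]) < 1e-14) vz[i] = 0.0;
        px[i] += dt * vx[i];
        py[i] += dt * vy[i];
        pz[i] += dt * vz[i];
      } else {
        vx[i] = vy[i] = vz[i] = 0.0;
      }
    }
    for (int k = 0; k < ng; ++k) {
      const size_t cn = gidx[k].size();
      std::vector<double> ox(cn), oy(cn), oz(cn);
      for (size_t r = 0; r < cn; ++r) {
        ox[r] = qx[gidx[k][r]]; oy[r] = qy[gidx[k][r]]; oz[r] = qz[gidx[k][r]];
      }
      project_rigid(px.data(), py.data(), pz.data(),
                    vx.data(), vy.data(), vz.data(),
                    gidx[k], gref[k], ox, oy, oz, dt);
    }
    for (int w = 0; w < nw; ++w) {
      px[wf[w]] = px[wa[w]]; py[wf[w]] = py[wa[w]]; pz[wf[w]] = pz[wa[w]];
      vx[wf[w]] = vx[wa[w]]; vy[wf[w]] = vy[wa[w]]; vz[wf[w]] = vz[wa[w]];
    }

    max_speed = 0.0;
    max_disp = 0.0;
    for (int i = 0; i < n; ++i) {
      const double sp2 = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      const double ddx = px[i] - qx[i], ddy = py[i] - qy[i], ddz = pz[i] - qz[i];
      const double dp2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (sp2 > max_speed) max_speed = sp2;
      if (dp2 > max_disp) max_disp = dp2;
    }
    max_speed = std::sqrt(max_speed);
    max_disp = std::sqrt(max_disp);
    if (record_energy) {
      double en = 0.0;
      for (int i = 0; i < n; ++i)
        en += 0.5 * ms[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      for (int e = 0; e < m; ++e) {
        const int a = ia[e], b = ib[e];
        const double dx = px[b] - px[a], dy = py[b] - py[a],
                     dz = pz[b] - pz[a];
        const double str = std::sqrt(dx * dx + dy * dy + dz * dz) - rl[e];
        en += 0.5 * kk[e] * str * str;
      }
      energies.push_back(en);
    }
    if (max_speed > speed_ceiling) {
      diverged = true;
      break;
    }
    if (check_convergence) {
      if (max_speed <= vtol && max_disp <= dtol) {
        if (++streak >= streak_needed || it == 0) {
          converged = true;  // immediate for an exact fixed point
          break;
        }
      } else {
        streak = 0;
      }
    }
  }

  double elastic = 0.0;
  for (int e = 0; e < m; ++e) {
    const int a = ia[e], b = ib[e];
    const double dx = px[b] - px[a], dy = py[b] - py[a], dz = pz[b] - pz[a];
    const double str = std::sqrt(dx * dx + dy * dy + dz * dz) - rl[e];
    elastic += 0.5 * kk[e] * str * str;
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = px[i]; pos_out(i, 1) = py[i]; pos_out(i, 2) = pz[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i]; vel_out(i, 2) = vz[i];
  }
  return List::create(
      _["pos"] = pos_out, _["vel"] = vel_out, _["steps"] = steps,
      _["converged"] = converged, _["diverged"] = diverged,
      _["max_speed"] = max_speed, _["max_disp"] = max_disp,
      _["elastic_energy"] = elastic,
      _["energy_trace"] = record_energy ? wrap(energies) : R_NilValue);
}
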