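// Core numerics for the C-alpha structure-based model: potential energy,
// analytic forces and a BAOAB Langevin integrator, all in reduced units
// (epsilon_0 = 1, k_B = 1, mass = 1, lengths in Angstrom).
//
// Conventions (documented in the package vignette):
//   bonds      V = k_b (r - r0)^2              (no 1/2 factor)
//   angles     V = k_a (theta - theta0)^2
//   dihedrals  V = k_d [(1 - cos(phi - phi0)) + 1/2 (1 - cos 3(phi - phi0))]
//   contacts   V = eps [5 (sigma/r)^12 - 6 (sigma/r)^10]
//   non-native V = eps_nn [(sigma_nn/r)^12 - 1]  for r < sigma_nn, else 0
//               (truncated and shifted so the native state, whose non-contact
//                pairs all sit beyond sigma_nn, has exactly V = -sum eps)
//   restraint  V = k_r max(0, |x - c| - R)^2   (optional soft sphere, used by
//                                              the synthetic-structure generator)

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>

using namespace Rcpp;

struct Topo {
  int n;
  std::vector<int> bi, bj;           std::vector<double> br0, bk;
  std::vector<int> ai, aj, ak;       std::vector<double> at0, aka;
  std::vector<int> di, dj, dk, dl;   std::vector<double> dp0, dkd;
  std::vector<int> ci, cj;           std::vector<double> csig, ceps;
  double sigma_nn, eps_nn;
  int nn_min_sep;
  std::vector<unsigned char> excl;   // n*n: pairs excluded from non-native term
  double rest_k, rest_R;
  double rest_cx, rest_cy, rest_cz;
};

static Topo parse_topo(const List& tl) {
  Topo t;
  t.n = as<int>(tl["n_beads"]);
  IntegerMatrix bonds = tl["bonds_idx"];        NumericMatrix bpar = tl["bonds_par"];
  IntegerMatrix angs  = tl["angles_idx"];       NumericMatrix apar = tl["angles_par"];
  IntegerMatrix dihs  = tl["dihedrals_idx"];    NumericMatrix dpar = tl["dihedrals_par"];
  IntegerMatrix cons  = tl["contacts_idx"];     NumericMatrix cpar = tl["contacts_par"];
  for (int r = 0; r < bonds.nrow(); ++r) {
    t.bi.push_back(bonds(r,0)); t.bj.push_back(bonds(r,1));
    t.br0.push_back(bpar(r,0)); t.bk.push_back(bpar(r,1));
  }
  for (int r = 0; r < angs.nrow(); ++r) {
    t.ai.push_back(angs(r,0)); t.aj.push_back(angs(r,1)); t.ak.push_back(angs(r,2));
    t.at0.push_back(apar(r,0)); t.aka.push_back(apar(r,1));
  }
  for (int r = 0; r < dihs.nrow(); ++r) {
    t.di.push_back(dihs(r,0)); t.dj.push_back(dihs(r,1));
    t.dk.push_back(dihs(r,2)); t.dl.push_back(dihs(r,3));
    t.dp0.push_back(dpar(r,0)); t.dkd.push_back(dpar(r,1));
  }
  for (int r = 0; r < cons.nrow(); ++r) {
    t.ci.push_back(cons(r,0)); t.cj.push_back(cons(r,1));
    t.csig.push_back(cpar(r,0)); t.ceps.push_back(cpar(r,1));
  }
  t.sigma_nn   = as<double>(tl["sigma_nn"]);
  t.eps_nn     = as<double>(tl["eps_nn"]);
  t.nn_min_sep = as<int>(tl["nn_min_sep"]);
  t.rest_k = as<double>(tl["restraint_k"]);
  t.rest_R = as<double>(tl["restraint_R"]);
  NumericVector rc = tl["restraint_center"];
  t.rest_cx = rc[0]; t.rest_cy = rc[1]; t.rest_cz = rc[2];
  // non-native exclusions: native contact pairs and explicit bond pairs
  t.excl.assign((size_t)t.n * t.n, 0);
  for (size_t c = 0; c < t.ci.size(); ++c) {
    t.excl[(size_t)t.ci[c] * t.n + t.cj[c]] = 1;
    t.excl[(size_t)t.cj[c] * t.n + t.ci[c]] = 1;
  }
  for (size_t b = 0; b < t.bi.size(); ++b) {
    t.excl[(size_t)t.bi[b] * t.n + t.bj[b]] = 1;
    t.excl[(size_t)t.bj[b] * t.n + t.bi[b]] = 1;
  }
  IntegerMatrix extra = tl["exclusions_idx"];
  for (int r = 0; r < extra.nrow(); ++r) {
    t.excl[(size_t)extra(r,0) * t.n + extra(r,1)] = 1;
    t.excl[(size_t)extra(r,1) * t.n + extra(r,0)] = 1;
  }
  return t;
}

// Energy terms and (optionally) forces. coords/force are length 3n (x,y,z per bead).
static void eval_all(const Topo& t, const double* x, double* f,
                     double& e_bond, double& e_ang, double& e_dih,
                     double& e_con, double& e_nn, double& e_rest) {
  const int n = t.n;
  e_bond = e_ang = e_dih = e_con = e_nn = e_rest = 0.0;
  if (f) std::fill(f, f + 3 * n, 0.0);

  // bonds
  for (size_t b = 0; b < t.bi.size(); ++b) {
    int i = t.bi[b], j = t.bj[b];
    double dx = x[3*j] - x[3*i], dy = x[3*j+1] - x[3*i+1], dz = x[3*j+2] - x[3*i+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double d = r - t.br0[b];
    e_bond += t.bk[b] * d * d;
    if (f && r > 1e-12) {
      double c = 2.0 * t.bk[b] * d / r;   // dV/dr / r
      f[3*i]   += c * dx; f[3*i+1] += c * dy; f[3*i+2] += c * dz;
      f[3*j]   -= c * dx; f[3*j+1] -= c * dy; f[3*j+2] -= c * dz;
    }
  }

  // angles
  for (size_t a = 0; a < t.ai.size(); ++a) {
    int i = t.ai[a], j = t.aj[a], k = t.ak[a];
    double ux = x[3*i] - x[3*j], uy = x[3*i+1] - x[3*j+1], uz = x[3*i+2] - x[3*j+2];
    double vx = x[3*k] - x[3*j], vy = x[3*k+1] - x[3*j+1], vz = x[3*k+2] - x[3*j+2];
    double lu = std::sqrt(ux*ux + uy*uy + uz*uz);
    double lv = std::sqrt(vx*vx + vy*vy + vz*vz);
    double ct = (ux*vx + uy*vy + uz*vz) / (lu * lv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double d = th - t.at0[a];
    e_ang += t.aka[a] * d * d;
    if (f) {
      double st = std::sqrt(std::max(1e-12, 1.0 - ct*ct));
      double dEdth = 2.0 * t.aka[a] * d;
      // dth/dxi = (ct*uhat - vhat) / (lu * st); F = -dEdth * dth/dx
      double gix = -dEdth * (ct*ux/lu - vx/lv) / (lu * st);
      double giy = -dEdth * (ct*uy/lu - vy/lv) / (lu * st);
      double giz = -dEdth * (ct*uz/lu - vz/lv) / (lu * st);
      double gkx = -dEdth * (ct*vx/lv - ux/lu) / (lv * st);
      double gky = -dEdth * (ct*vy/lv - uy/lu) / (lv * st);
      double gkz = -dEdth * (ct*vz/lv - uz/lu) / (lv * st);
      f[3*i] += gix; f[3*i+1] += giy; f[3*i+2] += giz;
      f[3*k] += gkx; f[3*k+1] += gky; f[3*k+2] += gkz;
      f[3*j] -= gix + gkx; f[3*j+1] -= giy + gky; f[3*j+2] -= giz + gkz;
    }
  }

  // dihedrals (GROMACS-style force decomposition)
  for (size_t d0 = 0; d0 < t.di.size(); ++d0) {
    int i = t.di[d0], j = t.dj[d0], k = t.dk[d0], l = t.dl[d0];
    double rijx = x[3*i]-x[3*j], rijy = x[3*i+1]-x[3*j+1], rijz = x[3*i+2]-x[3*j+2];
    double rkjx = x[3*k]-x[3*j], rkjy = x[3*k+1]-x[3*j+1], rkjz = x[3*k+2]-x[3*j+2];
    double rklx = x[3*k]-x[3*l], rkly = x[3*k+1]-x[3*l+1], rklz = x[3*k+2]-x[3*l+2];
    double mx = rijy*rkjz - rijz*rkjy, my = rijz*rkjx - rijx*rkjz, mz = rijx*rkjy - rijy*rkjx;
    double nx = rkjy*rklz - rkjz*rkly, ny = rkjz*rklx - rkjx*rklz, nz = rkjx*rkly - rkjy*rklx;
    double m2 = mx*mx + my*my + mz*mz, n2 = nx*nx + ny*ny + nz*nz;
    double lkj = std::sqrt(rkjx*rkjx + rkjy*rkjy + rkjz*rkjz);
    if (m2 < 1e-12 || n2 < 1e-12 || lkj < 1e-12) continue;  // degenerate
    double cx = my*nz - mz*ny, cy = mz*nx - mx*nz, cz = mx*ny - my*nx;
    double sinv = (cx*rkjx + cy*rkjy + cz*rkjz) / lkj;
    double cosv = mx*nx + my*ny + mz*nz;
    double phi = std::atan2(sinv, cosv);
    double dphi = phi - t.dp0[d0];
    e_dih += t.dkd[d0] * ((1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0*dphi)));
    if (f) {
      double dEdphi = t.dkd[d0] * (std::sin(dphi) + 1.5 * std::sin(3.0*dphi));
      double fix = -dEdphi * lkj / m2 * mx, fiy = -dEdphi * lkj / m2 * my, fiz = -dEdphi * lkj / m2 * mz;
      double flx =  dEdphi * lkj / n2 * nx, fly =  dEdphi * lkj / n2 * ny, flz =  dEdphi * lkj / n2 * nz;
      double p = (rijx*rkjx + rijy*rkjy + rijz*rkjz) / (lkj*lkj);
      double q = (rklx*rkjx + rkly*rkjy + rklz*rkjz) / (lkj*lkj);
      double tx = p*fix - q*flx, ty = p*fiy - q*fly, tz = p*fiz - q*flz;
      f[3*i] += fix; f[3*i+1] += fiy; f[3*i+2] += fiz;
      f[3*l] += flx; f[3*l+1] += fly; f[3*l+2] += flz;
      f[3*j] += -fix + tx; f[3*j+1] += -fiy + ty; f[3*j+2] += -fiz + tz;
      f[3*k] += -flx - tx; f[3*k+1] += -fly - ty; f[3*k+2] += -flz - tz;
    }
  }

  // native contacts: 10-12 well, evaluated at all distances
  for (size_t c = 0; c < t.ci.size(); ++c) {
    int i = t.ci[c], j = t.cj[c];
    double dx = x[3*j] - x[3*i], dy = x[3*j+1] - x[3*i+1], dz = x[3*j+2] - x[3*i+2];
    double r2 = dx*dx + dy*dy + dz*dz;
    double s2 = t.csig[c] * t.csig[c] / r2;
    double s10 = s2*s2*s2*s2*s2, s12 = s10*s2;
    e_con += t.ceps[c] * (5.0 * s12 - 6.0 * s10);
    if (f) {
      // dV/dr * (1/r) = eps * (-60 s12 + 60 s10) / r2
      double cfo = t.ceps[c] * 60.0 * (s10 - s12) / r2;
      f[3*i]   += cfo * dx; f[3*i+1] += cfo * dy; f[3*i+2] += cfo * dz;
      f[3*j]   -= cfo * dx; f[3*j+1] -= cfo * dy; f[3*j+2] -= cfo * dz;
    }
  }

  // non-native excluded volume (truncated/shifted at sigma_nn)
  const double s2cut = t.sigma_nn * t.sigma_nn;
  for (int i = 0; i < n; ++i) {
    for (int j = i + t.nn_min_sep; j < n; ++j) {
      if (t.excl[(size_t)i * n + j]) continue;
      double dx = x[3*j] - x[3*i], dy = x[3*j+1] - x[3*i+1], dz = x[3*j+2] - x[3*i+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= s2cut) continue;
      double s2 = s2cut / r2;
      double s12 = s2*s2*s2; s12 = s12*s12;
      e_nn += t.eps_nn * (s12 - 1.0);
      if (f) {
        double cfo = -t.eps_nn * 12.0 * s12 / r2;
        f[3*i]   += cfo * dx; f[3*i+1] += cfo * dy; f[3*i+2] += cfo * dz;
        f[3*j]   -= cfo * dx; f[3*j+1] -= cfo * dy; f[3*j+2] -= cfo * dz;
      }
    }
  }

  // optional spherical restraint
  if (t.rest_k > 0) {
    for (int i = 0; i < n; ++i) {
      double dx = x[3*i] - t.rest_cx, dy = x[3*i+1] - t.rest_cy, dz = x[3*i+2] - t.rest_cz;
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r > t.rest_R) {
        double d = r - t.rest_R;
        e_rest += t.rest_k * d * d;
        if (f && r > 1e-12) {
          double c = -2.0 * t.rest_k * d / r;
          f[3*i] += c * dx; f[3*i+1] += c * dy; f[3*i+2] += c * dz;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List sbm_energy_cpp(List topo, NumericMatrix coords) {
  Topo t = parse_topo(topo);
  if (coords.nrow() != t.n) stop("coords must have one row per bead");
  for (int i = 0; i < coords.length(); ++i)
    if (!R_finite(coords[i])) stop("non-finite coordinates");
  std::vector<double> x(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i, d);
  double eb, ea, ed, ec, en, er;
  eval_all(t, x.data(), nullptr, eb, ea, ed, ec, en, er);
  return List::create(_["total"] = eb + ea + ed + ec + en + er,
                      _["bonds"] = eb, _["angles"] = ea, _["dihedrals"] = ed,
                      _["contacts"] = ec, _["nonnative"] = en, _["restraint"] = er);
}

// [[Rcpp::export]]
NumericMatrix sbm_forces_cpp(List topo, NumericMatrix coords) {
  Topo t = parse_topo(topo);
  if (coords.nrow() != t.n) stop("coords must have one row per bead");
  for (int i = 0; i < coords.length(); ++i)
    if (!R_finite(coords[i])) stop("non-finite coordinates");
  std::vector<double> x(3 * t.n), f(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i, d);
  double eb, ea, ed, ec, en, er;
  eval_all(t, x.data(), f.data(), eb, ea, ed, ec, en, er);
  NumericMatrix out(t.n, 3);
  for (int i = 0; i < t.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = f[3*i+d];
  return out;
}

// BAOAB Langevin leapfrog; friction <= 0 switches to velocity-Verlet NVE.
// [[Rcpp::export]]
List sbm_run_langevin_cpp(List topo, NumericMatrix coords0, double T,
                          int n_steps, double dt, double friction,
                          int seed, int save_every) {
  Topo t = parse_topo(topo);
  const int n = t.n;
  if (coords0.nrow() != n) stop("coords0 must have one row per bead");
  std::vector<double> x(3*n), v(3*n, 0.0), f(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords0(i, d);

  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  const bool nve = friction <= 0.0;
  const double c1 = nve ? 1.0 : std::exp(-friction * dt);
  const double c2 = nve ? 0.0 : std::sqrt((1.0 - c1 * c1) * T);

  // Maxwell-Boltzmann start velocities (zeroed centre-of-mass drift)
  if (T > 0) {
    double mvx = 0, mvy = 0, mvz = 0;
    for (int i = 0; i < n; ++i) {
      v[3*i]   = std::sqrt(T) * gauss(rng);
      v[3*i+1] = std::sqrt(T) * gauss(rng);
      v[3*i+2] = std::sqrt(T) * gauss(rng);
      mvx += v[3*i]; mvy += v[3*i+1]; mvz += v[3*i+2];
    }
    for (int i = 0; i < n; ++i) {
      v[3*i] -= mvx / n; v[3*i+1] -= mvy / n; v[3*i+2] -= mvz / n;
    }
  }

  double eb, ea, ed, ec, en, er;
  eval_all(t, x.data(), f.data(), eb, ea, ed, ec, en, er);

  int n_save = n_steps / save_every;
  NumericVector frames(Dimension(n, 3, n_save));
  NumericVector epot(n_save), ekin(n_save);
  IntegerVector steps(n_save);
  int isave = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < 3*n; ++i) v[i] += 0.5 * dt * f[i];
    // A
    for (int i = 0; i < 3*n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (!nve) for (int i = 0; i < 3*n; ++i) v[i] = c1 * v[i] + c2 * gauss(rng);
    // A
    for (int i = 0; i < 3*n; ++i) x[i] += 0.5 * dt * v[i];
    // force update + B
    eval_all(t, x.data(), f.data(), eb, ea, ed, ec, en, er);
    for (int i = 0; i < 3*n; ++i) v[i] += 0.5 * dt * f[i];

    if (step % save_every == 0) {
      double ep = eb + ea + ed + ec + en + er;
      double ek = 0;
      for (int i = 0; i < 3*n; ++i) ek += 0.5 * v[i] * v[i];
      if (!R_finite(ep) || !R_finite(ek))
        stop("numerical blow-up at step %d (non-finite energy)", step);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(size_t)isave * 3 * n + (size_t)d * n + i] = x[3*i+d];
      epot[isave] = ep; ekin[isave] = ek; steps[isave] = step;
      ++isave;
    }
  }

  NumericMatrix xfin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) xfin(i, d) = x[3*i+d];

  return List::create(_["frames"] = frames, _["potential_energy"] = epot,
                      _["kinetic_energy"] = ekin, _["step_indices"] = steps,
                      _["final_coords"] = xfin);
}

// Per-frame distances for a list of (i, j) pairs; frames is n x 3 x nf.
// [[Rcpp::export]]
NumericMatrix pair_distance_series_cpp(NumericVector frames, IntegerVector i,
                                       IntegerVector j) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  int np = i.size();
  NumericMatrix out(nf, np);
  for (int fidx = 0; fidx < nf; ++fidx) {
    size_t base = (size_t)fidx * 3 * n;
    for (int p = 0; p < np; ++p) {
      int a = i[p], b = j[p];
      double dx = frames[base + 0*n + a] - frames[base + 0*n + b];
      double dy = frames[base + 1*n + a] - frames[base + 1*n + b];
      double dz = frames[base + 2*n + a] - frames[base + 2*n + b];
      out(fidx, p) = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
  }
  return out;
}
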