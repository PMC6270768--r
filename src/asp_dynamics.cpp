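#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Internal units: length A, energy kcal/mol, mass Da (amu), time ps.
// 1 (kcal/mol/A)/amu = 418.4 A/ps^2.
static const double FCONV = 418.4;
static const double KBOLTZ = 0.0019872041; // kcal/mol/K

struct LJParamsC {
  double eps_aa, rmin_aa;   // ASP particle - ASP particle
  double eps_ap, rmin_ap;   // ASP particle - protein atom
  double cutoff2;
  bool aa_on;               // ASP-ASP LJ active at all
  double core_frac;         // linearised soft core below core_frac * rmin
  bool ap_wca;              // particle-protein: repulsive-only (WCA) LJ
};

// 12-6 LJ in rmin form: E = eps * ((rmin/r)^12 - 2 (rmin/r)^6).
// Returns dE/d(r2); pair force on i is -2 * dEdr2 * (xi - xj).
// Below r_core = core_frac * rmin the potential continues linearly
// (constant force matching the boundary), so that freshly activated
// lattice particles overlapping other matter push with a large but finite
// force instead of the divergent 12-6 wall.
static inline double lj_pair_e_dedr2(double r2, double eps, double rmin,
                                     double core_frac, double &energy) {
  if (core_frac > 0.0) {
    double rc = core_frac * rmin;
    if (r2 < rc * rc) {
      double s6c = 1.0 / (core_frac * core_frac * core_frac *
                          core_frac * core_frac * core_frac);
      double ec = eps * (s6c * s6c - 2.0 * s6c);
      double fc = 12.0 * eps * (s6c * s6c - s6c) / rc;  // -dE/dr at rc (>0)
      double r = std::sqrt(r2);
      energy += ec + fc * (rc - r);
      return -fc / (2.0 * r);   // dE/dr = -fc
    }
  }
  double inv_r2 = 1.0 / r2;
  double rm2 = rmin * rmin * inv_r2;
  double s6 = rm2 * rm2 * rm2;
  energy += eps * (s6 * s6 - 2.0 * s6);
  return -6.0 * eps * s6 * (s6 - 1.0) * inv_r2;
}


static std::vector<int> to_ivec(const IntegerVector &v) {
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> to_dvec(const NumericVector &v) {
  return std::vector<double>(v.begin(), v.end());
}

// Forces and potential energy for the interacting set.
// kind: 0 = protein atom (ENM node), 1 = active ASP particle.
// Pair terms: ENM springs (given explicitly), LJ for pairs with >= 1 ASP
// particle (protein-protein is springs only), harmonic anchors.
static void forces_energy(const std::vector<double> &px,
                          const std::vector<double> &py,
                          const std::vector<double> &pz,
                          const std::vector<int> &kind,
                          const std::vector<int> &sp_i, const std::vector<int> &sp_j,
                          const std::vector<double> &sp_r0, const std::vector<double> &sp_k,
                          const std::vector<double> &ax, const std::vector<double> &ay,
                          const std::vector<double> &az, const std::vector<double> &ak,
                          const LJParamsC &lj,
                          std::vector<double> &fx, std::vector<double> &fy,
                          std::vector<double> &fz,
                          double &e_spring, double &e_lj, double &e_anchor) {
  const int n = (int)px.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  e_spring = e_lj = e_anchor = 0.0;

  // ENM springs
  const int ns = (int)sp_i.size();
  for (int s = 0; s < ns; ++s) {
    int i = sp_i[s], j = sp_j[s];
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - sp_r0[s];
    e_spring += 0.5 * sp_k[s] * dr * dr;
    if (r > 1e-12) {
      double c = -sp_k[s] * dr / r;
      fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
      fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
    }
  }

  // LJ pairs involving at least one ASP particle
  bool any_protein = false;
  for (int i = 0; i < n; ++i) if (kind[i] == 0) { any_protein = true; break; }
  if (!lj.aa_on && !any_protein) goto anchors;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int nasp = kind[i] + kind[j];
      if (nasp == 0) continue;                  // protein-protein: ENM only
      if (nasp == 2 && !lj.aa_on) continue;
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > lj.cutoff2 || r2 < 1e-12) continue;
      double dedr2;
      if (nasp == 2) {
        dedr2 = lj_pair_e_dedr2(r2, lj.eps_aa, lj.rmin_aa, lj.core_frac, e_lj);
      } else {
        if (lj.ap_wca && r2 >= lj.rmin_ap * lj.rmin_ap) continue;
        dedr2 = lj_pair_e_dedr2(r2, lj.eps_ap, lj.rmin_ap, lj.core_frac, e_lj);
        if (lj.ap_wca) e_lj += lj.eps_ap;   // WCA energy shift
      }
      double c = -2.0 * dedr2;
      fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
      fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
    }
  }

  // Harmonic anchors
anchors:
  for (int i = 0; i < n; ++i) {
    if (ak[i] <= 0.0) continue;
    double dx = px[i] - ax[i], dy = py[i] - ay[i], dz = pz[i] - az[i];
    e_anchor += 0.5 * ak[i] * (dx * dx + dy * dy + dz * dz);
    fx[i] -= ak[i] * dx; fy[i] -= ak[i] * dy; fz[i] -= ak[i] * dz;
  }
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, IntegerVector kind,
                IntegerVector sp_i, IntegerVector sp_j,
                NumericVector sp_r0, NumericVector sp_k,
                NumericMatrix anchors, NumericVector anchor_k,
                double eps_aa, double rmin_aa, double eps_ap, double rmin_ap,
                double cutoff, bool aa_on, double core_frac, bool ap_wca) {
  const int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n), fx(n), fy(n), fz(n), ak(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    ak[i] = anchor_k[i];
  }
  LJParamsC lj{eps_aa, rmin_aa, eps_ap, rmin_ap, cutoff * cutoff, aa_on, core_frac, ap_wca};
  double es, el, ea;
  forces_energy(px, py, pz, to_ivec(kind), to_ivec(sp_i), to_ivec(sp_j),
                to_dvec(sp_r0), to_dvec(sp_k),
                to_dvec(anchors(_, 0)), to_dvec(anchors(_, 1)),
                to_dvec(anchors(_, 2)), ak, lj,
                fx, fy, fz, es, el, ea);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["forces"] = F,
                      _["energy"] = es + el + ea,
                      _["energy_spring"] = es,
                      _["energy_lj"] = el,
                      _["energy_anchor"] = ea);
}

// One-way probe forces: net LJ force magnitude on each fixed probe from the
// protein (always) and from active ASP particles (if feel_active).
static void probe_force_mags(const std::vector<double> &px,
                             const std::vector<double> &py,
                             const std::vector<double> &pz,
                             const std::vector<int> &kind,
                             const std::vector<double> &qxv,
                             const std::vector<double> &qyv,
                             const std::vector<double> &qzv,
                             const LJParamsC &lj, bool feel_active,
                             std::vector<double> &mag) {
  const int n = (int)px.size();
  const int np = (int)qxv.size();
  bool any_protein = false;
  for (int i = 0; i < n; ++i) if (kind[i] == 0) { any_protein = true; break; }
  if (!any_protein && (!feel_active || !lj.aa_on)) {
    std::fill(mag.begin(), mag.end(), 0.0);
    return;
  }
  for (int p = 0; p < np; ++p) {
    double fx = 0.0, fy = 0.0, fz = 0.0, e = 0.0;
    double qx = qxv[p], qy = qyv[p], qz = qzv[p];
    for (int j = 0; j < n; ++j) {
      if (kind[j] == 1) {
        if (!feel_active || !lj.aa_on) continue;
      }
      double dx = qx - px[j], dy = qy - py[j], dz = qz - pz[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > lj.cutoff2 || r2 < 1e-12) continue;
      double dedr2;
      if (kind[j] == 1) {
        dedr2 = lj_pair_e_dedr2(r2, lj.eps_aa, lj.rmin_aa, lj.core_frac, e);
      } else {
        if (lj.ap_wca && r2 >= lj.rmin_ap * lj.rmin_ap) continue;
        dedr2 = lj_pair_e_dedr2(r2, lj.eps_ap, lj.rmin_ap, lj.core_frac, e);
      }
      double c = -2.0 * dedr2;
      fx += c * dx; fy += c * dy; fz += c * dz;
    }
    mag[p] = std::sqrt(fx * fx + fy * fy + fz * fz);
  }
}

// [[Rcpp::export]]
NumericVector cpp_probe_forces(NumericMatrix pos, IntegerVector kind,
                               NumericMatrix probe,
                               double eps_aa, double rmin_aa,
                               double eps_ap, double rmin_ap,
                               double cutoff, bool aa_on, double core_frac, bool ap_wca,
                               bool feel_active) {
  const int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2); }
  LJParamsC lj{eps_aa, rmin_aa, eps_ap, rmin_ap, cutoff * cutoff, aa_on, core_frac, ap_wca};
  std::vector<double> mag(probe.nrow(), 0.0);
  probe_force_mags(px, py, pz, to_ivec(kind), to_dvec(probe(_, 0)),
                   to_dvec(probe(_, 1)), to_dvec(probe(_, 2)),
                   lj, feel_active, mag);
  return NumericVector(mag.begin(), mag.end());
}

// BAOAB Langevin / velocity-Verlet integrator over n_steps.
// Mobile particles move; non-mobile are fixed. Temperature and per-particle
// anchor force constants are linearly interpolated from *_start to *_end
// over the call (heating ramp / restraint release). gamma <= 0 or
// langevin = false gives plain NVE velocity Verlet.
// Probes (fixed positions) accumulate the time-averaged net LJ force
// magnitude, sampled every step after the position update.
// [[Rcpp::export]]
List cpp_integrate(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                   LogicalVector mobile, IntegerVector kind,
                   IntegerVector sp_i, IntegerVector sp_j,
                   NumericVector sp_r0, NumericVector sp_k,
                   NumericMatrix anchors,
                   NumericVector anchor_k_start, NumericVector anchor_k_end,
                   double eps_aa, double rmin_aa, double eps_ap, double rmin_ap,
                   double cutoff, bool aa_on, double core_frac, bool ap_wca,
                   double dt, int n_steps, bool langevin, double gamma,
                   double temp_start, double temp_end,
                   NumericMatrix probe, bool feel_active) {
  const int n = pos.nrow();
  const int np = probe.nrow();
  std::vector<double> px(n), py(n), pz(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n), fy(n), fz(n), ak(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    ak[i] = anchor_k_start[i];
  }
  LJParamsC lj{eps_aa, rmin_aa, eps_ap, rmin_ap, cutoff * cutoff, aa_on, core_frac, ap_wca};
  std::vector<int> kindv = to_ivec(kind), spi = to_ivec(sp_i), spj = to_ivec(sp_j);
  std::vector<double> spr0 = to_dvec(sp_r0), spk = to_dvec(sp_k);
  std::vector<double> axv = to_dvec(anchors(_, 0)), ayv = to_dvec(anchors(_, 1)),
                      azv = to_dvec(anchors(_, 2));
  std::vector<double> aks = to_dvec(anchor_k_start), ake = to_dvec(anchor_k_end);
  std::vector<double> qx = to_dvec(probe(_, 0)), qy = to_dvec(probe(_, 1)),
                      qz = to_dvec(probe(_, 2));
  std::vector<double> mvec(n), invm(n);
  std::vector<char> mob(n);
  bool ramp_k = false;
  for (int i = 0; i < n; ++i) {
    mvec[i] = mass[i]; invm[i] = 1.0 / mass[i]; mob[i] = mobile[i] ? 1 : 0;
    if (aks[i] != ake[i]) ramp_k = true;
  }
  std::vector<double> acc_mag(np, 0.0), mag(np, 0.0);

  double es, el, ea;
  forces_energy(px, py, pz, kindv, spi, spj, spr0, spk,
                axv, ayv, azv, ak, lj, fx, fy, fz, es, el, ea);

  double c1 = (langevin && gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  bool ok = true;

  for (int step = 0; step < n_steps; ++step) {
    double frac = (n_steps > 1) ? (double)step / (double)(n_steps - 1) : 1.0;
    double temp = temp_start + (temp_end - temp_start) * frac;
    if (ramp_k)
      for (int i = 0; i < n; ++i) ak[i] = aks[i] + (ake[i] - aks[i]) * frac;

    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (!mob[i]) continue;
      double s = 0.5 * dt * FCONV * invm[i];
      vx[i] += s * fx[i]; vy[i] += s * fy[i]; vz[i] += s * fz[i];
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (!mob[i]) continue;
      px[i] += 0.5 * dt * vx[i]; py[i] += 0.5 * dt * vy[i]; pz[i] += 0.5 * dt * vz[i];
    }
    // O: Ornstein-Uhlenbeck
    if (langevin && gamma > 0.0) {
      double kbt = KBOLTZ * std::max(0.0, temp) * FCONV;
      for (int i = 0; i < n; ++i) {
        if (!mob[i]) continue;
        double sigma = std::sqrt(kbt * invm[i]);
        vx[i] = c1 * vx[i] + c2 * sigma * R::norm_rand();
        vy[i] = c1 * vy[i] + c2 * sigma * R::norm_rand();
        vz[i] = c1 * vz[i] + c2 * sigma * R::norm_rand();
      }
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (!mob[i]) continue;
      px[i] += 0.5 * dt * vx[i]; py[i] += 0.5 * dt * vy[i]; pz[i] += 0.5 * dt * vz[i];
    }
    // recompute forces, B: half kick
    forces_energy(px, py, pz, kindv, spi, spj, spr0, spk,
                  axv, ayv, azv, ak, lj, fx, fy, fz, es, el, ea);
    for (int i = 0; i < n; ++i) {
      if (!mob[i]) continue;
      double s = 0.5 * dt * FCONV * invm[i];
      vx[i] += s * fx[i]; vy[i] += s * fy[i]; vz[i] += s * fz[i];
    }

    if (np > 0) {
      probe_force_mags(px, py, pz, kindv, qx, qy, qz, lj, feel_active, mag);
      for (int p = 0; p < np; ++p) acc_mag[p] += mag[p];
    }

    if ((step & 127) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(px[i]) || !std::isfinite(vx[i])) { ok = false; break; }
      if (!ok) break;
    }
  }
  for (int i = 0; i < n && ok; ++i)
    if (!std::isfinite(px[i]) || !std::isfinite(py[i]) || !std::isfinite(pz[i]))
      ok = false;

  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    pout(i, 0) = px[i]; pout(i, 1) = py[i]; pout(i, 2) = pz[i];
    vout(i, 0) = vx[i]; vout(i, 1) = vy[i]; vout(i, 2) = vz[i];
  }
  NumericVector pf(np);
  for (int p = 0; p < np; ++p) pf[p] = n_steps > 0 ? acc_mag[p] / n_steps : 0.0;
  return List::create(_["pos"] = pout, _["vel"] = vout,
                      _["probe_mean_force"] = pf,
                      _["energy"] = es + el + ea, _["ok"] = ok);
}
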