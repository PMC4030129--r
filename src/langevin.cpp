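#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// BAOAB Langevin integration of a harmonic elastic network.
// Units: kcal/mol, Angstrom, amu, ps. Gaussians come from R's RNG so a
// set.seed() in the caller makes the trajectory bit-identical.

static const double KCAL_TO_AKMA = 418.4;   // kcal/mol -> amu A^2 ps^-2
static const double KB_KCAL = 0.0019872041; // kcal mol^-1 K^-1

static void enm_forces(const std::vector<double>& x,
                       const IntegerVector& ei, const IntegerVector& ej,
                       const NumericVector& k, const NumericVector& r0,
                       std::vector<double>& f) {
  std::fill(f.begin(), f.end(), 0.0);
  const int ne = ei.size();
  for (int e = 0; e < ne; ++e) {
    const int i = ei[e], j = ej[e];
    const double dx = x[3 * j] - x[3 * i];
    const double dy = x[3 * j + 1] - x[3 * i + 1];
    const double dz = x[3 * j + 2] - x[3 * i + 2];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-10) continue; // singular geometry; caught as divergence later
    const double s = k[e] * (r - r0[e]) / r; // force on i along +d
    f[3 * i] += s * dx;     f[3 * j] -= s * dx;
    f[3 * i + 1] += s * dy; f[3 * j + 1] -= s * dy;
    f[3 * i + 2] += s * dz; f[3 * j + 2] -= s * dz;
  }
}

static void remove_com(std::vector<double>& v, const NumericVector& mass,
                       double mtot) {
  const int n = mass.size();
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) {
    cx += mass[i] * v[3 * i];
    cy += mass[i] * v[3 * i + 1];
    cz += mass[i] * v[3 * i + 2];
  }
  cx /= mtot; cy /= mtot; cz /= mtot;
  for (int i = 0; i < n; ++i) {
    v[3 * i] -= cx; v[3 * i + 1] -= cy; v[3 * i + 2] -= cz;
  }
}

// [[Rcpp::export(name = ".langevinRun")]]
List langevinRun(NumericVector x0, IntegerVector ei, IntegerVector ej,
                 NumericVector k, NumericVector r0, NumericVector mass,
                 double dt, int nSteps, double temperature, double friction,
                 int saveEvery) {
  RNGScope scope;
  const int n = mass.size();
  const int dof = 3 * n;
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(dof), f(dof);
  double mtot = 0;
  for (int i = 0; i < n; ++i) mtot += mass[i];

  // Maxwell-Boltzmann initial velocities, net momentum removed
  for (int i = 0; i < n; ++i) {
    const double sd = std::sqrt(KB_KCAL * temperature * KCAL_TO_AKMA / mass[i]);
    v[3 * i] = sd * norm_rand();
    v[3 * i + 1] = sd * norm_rand();
    v[3 * i + 2] = sd * norm_rand();
  }
  if (temperature > 0) remove_com(v, mass, mtot);

  const double c1 = std::exp(-friction * dt);
  std::vector<double> c2(n), invm(n);
  for (int i = 0; i < n; ++i) {
    invm[i] = KCAL_TO_AKMA / mass[i];
    c2[i] = std::sqrt(KB_KCAL * temperature * KCAL_TO_AKMA / mass[i] *
                      (1.0 - c1 * c1));
  }

  const int nSave = nSteps / saveEvery;
  NumericMatrix xyz(nSave, dof), vel(nSave, dof);
  int frame = 0, divergedStep = 0;

  // reference COM for drift removal
  double rx = 0, ry = 0, rz = 0;
  for (int i = 0; i < n; ++i) {
    rx += mass[i] * x[3 * i];
    ry += mass[i] * x[3 * i + 1];
    rz += mass[i] * x[3 * i + 2];
  }
  rx /= mtot; ry /= mtot; rz /= mtot;

  enm_forces(x, ei, ej, k, r0, f);
  for (int step = 1; step <= nSteps; ++step) {
    // B: half kick
    for (int d = 0; d < dof; ++d) v[d] += 0.5 * dt * f[d] * invm[d / 3];
    // A: half drift
    for (int d = 0; d < dof; ++d) x[d] += 0.5 * dt * v[d];
    // O: Ornstein-Uhlenbeck
    if (friction > 0) {
      for (int i = 0; i < n; ++i) {
        v[3 * i] = c1 * v[3 * i] + c2[i] * norm_rand();
        v[3 * i + 1] = c1 * v[3 * i + 1] + c2[i] * norm_rand();
        v[3 * i + 2] = c1 * v[3 * i + 2] + c2[i] * norm_rand();
      }
    }
    // A: half drift
    for (int d = 0; d < dof; ++d) x[d] += 0.5 * dt * v[d];
    // B: half kick with new forces
    enm_forces(x, ei, ej, k, r0, f);
    for (int d = 0; d < dof; ++d) v[d] += 0.5 * dt * f[d] * invm[d / 3];

    if (step % saveEvery == 0) {
      // remove center-of-mass drift (position and momentum)
      double cx = 0, cy = 0, cz = 0;
      for (int i = 0; i < n; ++i) {
        cx += mass[i] * x[3 * i];
        cy += mass[i] * x[3 * i + 1];
        cz += mass[i] * x[3 * i + 2];
      }
      cx = cx / mtot - rx; cy = cy / mtot - ry; cz = cz / mtot - rz;
      for (int i = 0; i < n; ++i) {
        x[3 * i] -= cx; x[3 * i + 1] -= cy; x[3 * i + 2] -= cz;
      }
      if (friction > 0 && temperature > 0) remove_com(v, mass, mtot);
      bool bad = false;
      for (int d = 0; d < dof; ++d)
        if (!std::isfinite(x[d])) { bad = true; break; }
      if (bad) { divergedStep = step; break; }
      for (int d = 0; d < dof; ++d) {
        xyz(frame, d) = x[d];
        vel(frame, d) = v[d];
      }
      ++frame;
    }
  }
  return List::create(_["xyz"] = xyz, _["vel"] = vel,
                      _["frames"] = frame, _["divergedStep"] = divergedStep);
}
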