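// Langevin (BAOAB) integration of toy potentials under a moving harmonic
// steering guide, with trapezoidal external-work accounting.
//
// Unit system: Angstrom, picosecond, amu, kcal/mol.
// 1 kcal/mol = 4184 J/mol = 418.4 amu A^2 / ps^2.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double EKCAL = 418.4;  // amu A^2 ps^-2 per kcal/mol

enum Kind {
  KIND_FREE = 0,
  KIND_HARMONIC = 1,
  KIND_DOUBLE_WELL = 2,
  KIND_TILTED_DOUBLE_WELL = 3,
  KIND_BEAD_SPRING_HELIX = 4
};

static inline double dist3(const std::vector<double>& x, int i, int j) {
  double dx = x[3 * j] - x[3 * i];
  double dy = x[3 * j + 1] - x[3 * i + 1];
  double dz = x[3 * j + 2] - x[3 * i + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static double pot_energy(int kind, const NumericVector& p,
                         const std::vector<double>& x) {
  const int dim = (int)x.size();
  switch (kind) {
  case KIND_FREE:
    return 0.0;
  case KIND_HARMONIC: {
    double a = p[0], e = 0.0;
    for (int i = 0; i < dim; ++i) e += 0.5 * a * x[i] * x[i];
    return e;
  }
  case KIND_DOUBLE_WELL: {
    double h = p[0], w = p[1];
    double s = x[0] / w, q = s * s - 1.0;
    return h * q * q;
  }
  case KIND_TILTED_DOUBLE_WELL: {
    double h = p[0], w = p[1], c = p[2];
    double s = x[0] / w, q = s * s - 1.0;
    return h * q * q + c * x[0];
  }
  case KIND_BEAD_SPRING_HELIX: {
    int nb = (int)p[0];
    double kb = p[1], r0 = p[2], eps = p[3], rc = p[4], sc = p[5];
    double e = 0.0;
    for (int i = 0; i + 1 < nb; ++i) {
      double d = dist3(x, i, i + 1) - r0;
      e += 0.5 * kb * d * d;
    }
    for (int i = 0; i + 4 < nb; ++i) {
      double d = dist3(x, i, i + 4) - rc;
      e -= eps * std::exp(-0.5 * d * d / (sc * sc));
    }
    return e;
  }
  }
  stop("unknown potential kind code");
  return NA_REAL;
}

// accumulate -dU/dx into f (i.e. f += force)
static void pot_force(int kind, const NumericVector& p,
                      const std::vector<double>& x, std::vector<double>& f) {
  const int dim = (int)x.size();
  switch (kind) {
  case KIND_FREE:
    return;
  case KIND_HARMONIC: {
    double a = p[0];
    for (int i = 0; i < dim; ++i) f[i] -= a * x[i];
    return;
  }
  case KIND_DOUBLE_WELL: {
    double h = p[0], w = p[1];
    double s = x[0] / w, q = s * s - 1.0;
    f[0] -= 4.0 * h * q * s / w;
    return;
  }
  case KIND_TILTED_DOUBLE_WELL: {
    double h = p[0], w = p[1], c = p[2];
    double s = x[0] / w, q = s * s - 1.0;
    f[0] -= 4.0 * h * q * s / w + c;
    return;
  }
  case KIND_BEAD_SPRING_HELIX: {
    int nb = (int)p[0];
    double kb = p[1], r0 = p[2], eps = p[3], rc = p[4], sc = p[5];
    for (int i = 0; i + 1 < nb; ++i) {
      double r = dist3(x, i, i + 1);
      if (r < 1e-12) continue;
      double coef = kb * (r - r0) / r;  // dU/dr / r
      for (int d = 0; d < 3; ++d) {
        double dx = x[3 * (i + 1) + d] - x[3 * i + d];
        f[3 * i + d] += coef * dx;
        f[3 * (i + 1) + d] -= coef * dx;
      }
    }
    for (int i = 0; i + 4 < nb; ++i) {
      double r = dist3(x, i, i + 4);
      if (r < 1e-12) continue;
      double d0 = r - rc;
      double dudr = eps * d0 / (sc * sc) * std::exp(-0.5 * d0 * d0 / (sc * sc));
      double coef = dudr / r;
      for (int d = 0; d < 3; ++d) {
        double dx = x[3 * (i + 4) + d] - x[3 * i + d];
        f[3 * i + d] += coef * dx;
        f[3 * (i + 4) + d] -= coef * dx;
      }
    }
    return;
  }
  }
  stop("unknown potential kind code");
}

// reaction coordinate: rc_type 0 = identity (x[0]); 1 = distance between
// beads ai and aj (0-based bead indices into a 3N coordinate vector)
static double rc_value(int rc_type, int ai, int aj,
                       const std::vector<double>& x) {
  if (rc_type == 0) return x[0];
  double r = dist3(x, ai, aj);
  if (r < 1e-12) stop("reaction coordinate undefined: tagged atoms coincide");
  return r;
}

// add guide force -k (xi - lambda) * grad(xi)
static void guide_force(int rc_type, int ai, int aj, double kspring,
                        double lambda, const std::vector<double>& x,
                        std::vector<double>& f, double* xi_out) {
  double xi = rc_value(rc_type, ai, aj, x);
  *xi_out = xi;
  double pref = -kspring * (xi - lambda);
  if (rc_type == 0) {
    f[0] += pref;
  } else {
    for (int d = 0; d < 3; ++d) {
      double u = (x[3 * aj + d] - x[3 * ai + d]) / xi;  // d xi / d x_aj
      f[3 * aj + d] += pref * u;
      f[3 * ai + d] -= pref * u;
    }
  }
}

struct Baoab {
  double dt;
  std::vector<double> c1, cnoise, invm;
  Baoab(const NumericVector& masses, double kT, double gamma, double dt_)
      : dt(dt_) {
    int n = masses.size();
    c1.resize(n);
    cnoise.resize(n);
    invm.resize(n);
    double e = std::exp(-gamma * dt_);
    for (int i = 0; i < n; ++i) {
      invm[i] = 1.0 / masses[i];
      c1[i] = e;
      cnoise[i] = std::sqrt((1.0 - e * e) * kT * EKCAL / masses[i]);
    }
  }
};

// One BAOAB step.  forces are in kcal/mol/A; velocities in A/ps.
// lam0: guide position for the first B half-kick, lam1 for the second.
// frozen dofs are held fixed (zero velocity, no update).
static void baoab_step(int kind, const NumericVector& p, int rc_type, int ai,
                       int aj, bool guide_on, double kspring, double lam0,
                       double lam1, const Baoab& st, std::vector<double>& x,
                       std::vector<double>& v, std::vector<double>& f,
                       const std::vector<int>& frozen, double* xi_out) {
  const int n = (int)x.size();
  double xi = NA_REAL;
  std::fill(f.begin(), f.end(), 0.0);
  pot_force(kind, p, x, f);
  if (guide_on) guide_force(rc_type, ai, aj, kspring, lam0, x, f, &xi);
  for (int i = 0; i < n; ++i) {
    if (frozen[i]) continue;
    v[i] += 0.5 * st.dt * f[i] * EKCAL * st.invm[i];
    x[i] += 0.5 * st.dt * v[i];
  }
  for (int i = 0; i < n; ++i) {
    double z = norm_rand();  // always drawn: keeps streams aligned across T
    if (frozen[i]) continue;
    v[i] = st.c1[i] * v[i] + st.cnoise[i] * z;
  }
  for (int i = 0; i < n; ++i) {
    if (frozen[i]) continue;
    x[i] += 0.5 * st.dt * v[i];
  }
  std::fill(f.begin(), f.end(), 0.0);
  pot_force(kind, p, x, f);
  if (guide_on) guide_force(rc_type, ai, aj, kspring, lam1, x, f, &xi);
  for (int i = 0; i < n; ++i) {
    if (frozen[i]) continue;
    v[i] += 0.5 * st.dt * f[i] * EKCAL * st.invm[i];
  }
  if (!guide_on) xi = rc_value(rc_type, ai, aj, x);
  *xi_out = xi;
}

static void check_finite(const std::vector<double>& x, double t) {
  for (size_t i = 0; i < x.size(); ++i) {
    if (!std::isfinite(x[i])) {
      stop("integration diverged: non-finite coordinate %d at t = %g ps",
           (int)(i + 1), t);
    }
  }
}

// [[Rcpp::export]]
double cpp_pot_energy(int kind, NumericVector params, NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  return pot_energy(kind, params, xv);
}

// [[Rcpp::export]]
NumericVector cpp_pot_gradient(int kind, NumericVector params,
                               NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> f(xv.size(), 0.0);
  pot_force(kind, params, xv, f);
  NumericVector g(xv.size());
  for (size_t i = 0; i < f.size(); ++i) g[i] = -f[i];
  return g;
}

// [[Rcpp::export]]
double cpp_rc_value(int rc_type, int ai, int aj, NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  return rc_value(rc_type, ai, aj, xv);
}

// Pull lambda from l0 to l1 at speed vpull [A/ps], accumulating external
// work dW = k (lambda - xi) vpull dt by the trapezoidal rule.  Work and xi
// are reported at the requested lambda grid (linear interpolation between
// integration steps; endpoints exact).
// [[Rcpp::export]]
List cpp_pull_segment(int kind, NumericVector params, NumericVector x0,
                      NumericVector v0, NumericVector masses, double kT,
                      double gamma, double dt, double kspring, double l0,
                      double l1, double vpull, NumericVector grid, int rc_type,
                      int ai, int aj) {
  const int n = x0.size();
  const int ngrid = grid.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> f(n, 0.0);
  std::vector<int> frozen(n, 0);
  Baoab st(masses, kT, gamma, dt);

  NumericVector W_rec(ngrid), xi_rec(ngrid);
  double t_total = (l1 - l0) / vpull;
  long nsteps = (long)std::ceil(t_total / dt - 1e-9);

  double W = 0.0;
  double xi = rc_value(rc_type, ai, aj, x);
  double g_prev = kspring * (l0 - xi) * vpull;
  double lam_prev = l0, W_prev = 0.0, xi_prev = xi;
  int ridx = 0;
  // leading grid points at or before l0 (normally just grid[0] == l0)
  while (ridx < ngrid && grid[ridx] <= l0 + 1e-12) {
    W_rec[ridx] = 0.0;
    xi_rec[ridx] = xi;
    ++ridx;
  }

  long nfull = (long)std::floor(t_total / dt + 1e-9);
  double dt_rem = t_total - nfull * dt;
  if (dt_rem < 1e-12) dt_rem = 0.0;
  nsteps = nfull + (dt_rem > 0 ? 1 : 0);
  Baoab st_rem(masses, kT, gamma, dt_rem > 0 ? dt_rem : dt);

  double t = 0.0;
  for (long s = 0; s < nsteps; ++s) {
    bool last = (s == nsteps - 1);
    double dt_s = (last && dt_rem > 0) ? dt_rem : dt;
    const Baoab* stp = (last && dt_rem > 0) ? &st_rem : &st;
    double lam0 = l0 + vpull * t;
    double t_new = last ? t_total : t + dt_s;
    double lam1 = last ? l1 : l0 + vpull * t_new;
    baoab_step(kind, params, rc_type, ai, aj, true, kspring, lam0, lam1, *stp,
               x, v, f, frozen, &xi);
    t = t_new;
    double g_now = kspring * (lam1 - xi) * vpull;
    W += 0.5 * (g_prev + g_now) * dt_s;
    if ((s & 1023) == 0) check_finite(x, t);
    while (ridx < ngrid && grid[ridx] <= lam1 + 1e-12) {
      double span = lam1 - lam_prev;
      double frac = span > 0 ? (grid[ridx] - lam_prev) / span : 1.0;
      if (frac < 0) frac = 0;
      if (frac > 1) frac = 1;
      W_rec[ridx] = W_prev + frac * (W - W_prev);
      xi_rec[ridx] = xi_prev + frac * (xi - xi_prev);
      ++ridx;
    }
    g_prev = g_now;
    lam_prev = lam1;
    W_prev = W;
    xi_prev = xi;
  }
  check_finite(x, t);
  if (ridx == ngrid - 1) {  // numeric guard: force-record the final endpoint
    W_rec[ridx] = W;
    xi_rec[ridx] = xi;
    ridx++;
  }
  if (ridx < ngrid) stop("record grid extends past lambda_end");

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["W"] = W_rec, _["xi"] = xi_rec,
                      _["work_end"] = W, _["t_elapsed"] = t,
                      _["nsteps"] = (double)nsteps);
}

// Fixed-lambda (or guide-free) integration for nsteps.  External work is
// exactly zero by construction (the guide, when active, does not move).
// frozen: 1-based dof indices to hold fixed.  energy_every > 0 records the
// total energy (potential + guide + kinetic) every that many steps.
// [[Rcpp::export]]
List cpp_hold_segment(int kind, NumericVector params, NumericVector x0,
                      NumericVector v0, NumericVector masses, double kT,
                      double gamma, double dt, double nsteps_d, bool guide_on,
                      double kspring, double lambda, int rc_type, int ai,
                      int aj, IntegerVector frozen_idx, int energy_every) {
  const int n = x0.size();
  long nsteps = (long)nsteps_d;
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> f(n, 0.0);
  std::vector<int> frozen(n, 0);
  for (int i = 0; i < frozen_idx.size(); ++i) {
    int k = frozen_idx[i] - 1;
    if (k < 0 || k >= n) stop("frozen dof index out of range");
    frozen[k] = 1;
    v[k] = 0.0;
  }
  Baoab st(masses, kT, gamma, dt);
  std::vector<double> etrace;
  double xi = rc_value(rc_type, ai, aj, x);
  if (energy_every > 0) {
    double e = pot_energy(kind, params, x);
    if (guide_on) e += 0.5 * kspring * (xi - lambda) * (xi - lambda);
    for (int i = 0; i < n; ++i) e += 0.5 * masses[i] * v[i] * v[i] / EKCAL;
    etrace.push_back(e);
  }
  for (long s = 0; s < nsteps; ++s) {
    baoab_step(kind, params, rc_type, ai, aj, guide_on, kspring, lambda,
               lambda, st, x, v, f, frozen, &xi);
    if ((s & 1023) == 0) check_finite(x, (s + 1) * dt);
    if (energy_every > 0 && ((s + 1) % energy_every == 0)) {
      double e = pot_energy(kind, params, x);
      if (guide_on) e += 0.5 * kspring * (xi - lambda) * (xi - lambda);
      for (int i = 0; i < n; ++i) e += 0.5 * masses[i] * v[i] * v[i] / EKCAL;
      etrace.push_back(e);
    }
  }
  check_finite(x, nsteps * dt);
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["work"] = 0.0, _["xi"] = xi,
                      _["t_elapsed"] = nsteps * dt,
                      _["energy"] = NumericVector(etrace.begin(),
                                                  etrace.end()));
}
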