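// Two-state EVB energy/force kernel and BAOAB Langevin integrator for the
// toy water-droplet sampler.  Units: kcal/mol, Angstrom, fs, amu, e.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0019872041;      // kcal/mol/K
static const double F2A = 4.184e-4;         // kcal/mol -> amu A^2 fs^-2

struct Prep {
  int n;
  NumericVector mass;
  NumericMatrix pairs1, pairs2, bonds1, bonds2, angles1, angles2;
  NumericMatrix buck, restraints, posres;
  IntegerVector confine_atoms;
  double confine_radius, confine_k;
  NumericVector confine_center;
};

static Prep unpack(const List& prep) {
  Prep p;
  p.n = as<int>(prep["n"]);
  p.mass = prep["mass"];
  p.pairs1 = as<NumericMatrix>(prep["pairs1"]);
  p.pairs2 = as<NumericMatrix>(prep["pairs2"]);
  p.bonds1 = as<NumericMatrix>(prep["bonds1"]);
  p.bonds2 = as<NumericMatrix>(prep["bonds2"]);
  p.angles1 = as<NumericMatrix>(prep["angles1"]);
  p.angles2 = as<NumericMatrix>(prep["angles2"]);
  p.buck = as<NumericMatrix>(prep["buck"]);
  p.restraints = as<NumericMatrix>(prep["restraints"]);
  p.posres = as<NumericMatrix>(prep["posres"]);
  p.confine_atoms = as<IntegerVector>(prep["confine_atoms"]);
  p.confine_radius = as<double>(prep["confine_radius"]);
  p.confine_k = as<double>(prep["confine_k"]);
  p.confine_center = as<NumericVector>(prep["confine_center"]);
  return p;
}

// add pairwise force f along (xi - xj)/r
static inline void add_pair_force(std::vector<double>& f, int i, int j,
                                  double fx, double fy, double fz) {
  f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
  f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
}

// nonbonded (Coulomb + LJ) for one state's pair list
static double nonbonded(const NumericMatrix& pr, const std::vector<double>& x,
                        std::vector<double>* f) {
  double e = 0.0;
  int m = pr.nrow();
  for (int r = 0; r < m; ++r) {
    int i = (int)pr(r, 0), j = (int)pr(r, 1);
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double qq = pr(r, 2);
    if (r2 < 1e-12 && qq != 0.0)
      stop("overlapping atoms %d and %d on a Coulomb pair (r < 1e-6 A)",
           i + 1, j + 1);
    double rinv2 = 1.0 / r2;
    double rinv = std::sqrt(rinv2);
    double ec = qq * rinv;
    double r6 = rinv2 * rinv2 * rinv2;
    double A = pr(r, 3), B = pr(r, 4);
    double elj = (A * r6 - B) * r6;
    e += ec + elj;
    if (f) {
      // dE/dr * (-1/r) components: F = -(dE/dr) rhat
      double fr = (ec + (12.0 * A * r6 - 6.0 * B) * r6) * rinv2; // -(dE/dr)/r
      add_pair_force(*f, i, j, fr * dx, fr * dy, fr * dz);
    }
  }
  return e;
}

static double buckingham(const NumericMatrix& bu, const std::vector<double>& x,
                         std::vector<double>* f) {
  double e = 0.0;
  for (int r = 0; r < bu.nrow(); ++r) {
    int i = (int)bu(r, 0), j = (int)bu(r, 1);
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-12)
      stop("overlapping atoms %d and %d on a Buckingham pair", i + 1, j + 1);
    double rr = std::sqrt(r2);
    double C = bu(r, 2), beta = bu(r, 3);
    double eb = C * std::exp(-beta * rr);
    e += eb;
    if (f) {
      double fr = beta * eb / rr;  // -(dE/dr)/r
      add_pair_force(*f, i, j, fr * dx, fr * dy, fr * dz);
    }
  }
  return e;
}

static double morse(const NumericMatrix& bd, const std::vector<double>& x,
                    std::vector<double>* f) {
  double e = 0.0;
  for (int r = 0; r < bd.nrow(); ++r) {
    int i = (int)bd(r, 0), j = (int)bd(r, 1);
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
    double D = bd(r, 2), beta = bd(r, 3), r0 = bd(r, 4);
    double ex = std::exp(-beta * (rr - r0));
    double om = 1.0 - ex;
    e += D * om * om;
    if (f) {
      double dEdr = 2.0 * D * beta * ex * om;
      double fr = -dEdr / rr;
      add_pair_force(*f, i, j, fr * dx, fr * dy, fr * dz);
    }
  }
  return e;
}

// harmonic angle E = k (theta - theta0)^2
static double angles(const NumericMatrix& an, const std::vector<double>& x,
                     std::vector<double>* f) {
  double e = 0.0;
  for (int r = 0; r < an.nrow(); ++r) {
    int i = (int)an(r, 0), j = (int)an(r, 1), k = (int)an(r, 2);
    double ax = x[3 * i] - x[3 * j], ay = x[3 * i + 1] - x[3 * j + 1],
           az = x[3 * i + 2] - x[3 * j + 2];
    double bx = x[3 * k] - x[3 * j], by = x[3 * k + 1] - x[3 * j + 1],
           bz = x[3 * k + 2] - x[3 * j + 2];
    double ra2 = ax * ax + ay * ay + az * az;
    double rb2 = bx * bx + by * by + bz * bz;
    double ra = std::sqrt(ra2), rb = std::sqrt(rb2);
    double dot = ax * bx + ay * by + az * bz;
    double cth = dot / (ra * rb);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    double th = std::acos(cth);
    double kth = an(r, 3), th0 = an(r, 4);
    double dth = th - th0;
    e += kth * dth * dth;
    if (f) {
      double sth = std::sqrt(1.0 - cth * cth);
      if (sth < 1e-8) sth = 1e-8;
      double dEdth = 2.0 * kth * dth;
      double coef = -dEdth / sth;  // dE/d(cos theta) = -dE/dth / sin(th)
      // d(cos)/dxi etc.
      double gx_i = (bx / (ra * rb)) - cth * ax / ra2;
      double gy_i = (by / (ra * rb)) - cth * ay / ra2;
      double gz_i = (bz / (ra * rb)) - cth * az / ra2;
      double gx_k = (ax / (ra * rb)) - cth * bx / rb2;
      double gy_k = (ay / (ra * rb)) - cth * by / rb2;
      double gz_k = (az / (ra * rb)) - cth * bz / rb2;
      (*f)[3 * i] -= coef * gx_i; (*f)[3 * i + 1] -= coef * gy_i;
      (*f)[3 * i + 2] -= coef * gz_i;
      (*f)[3 * k] -= coef * gx_k; (*f)[3 * k + 1] -= coef * gy_k;
      (*f)[3 * k + 2] -= coef * gz_k;
      (*f)[3 * j] += coef * (gx_i + gx_k);
      (*f)[3 * j + 1] += coef * (gy_i + gy_k);
      (*f)[3 * j + 2] += coef * (gz_i + gz_k);
    }
  }
  return e;
}

// flat-bottom pair restraints: E = k (r - bound)^2 outside [lower, upper]
static double flatbottom(const NumericMatrix& re, const std::vector<double>& x,
                         std::vector<double>* f) {
  double e = 0.0;
  for (int r = 0; r < re.nrow(); ++r) {
    int i = (int)re(r, 0), j = (int)re(r, 1);
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
    double lo = re(r, 2), hi = re(r, 3), k = re(r, 4);
    double ex = 0.0;
    if (rr < lo) ex = rr - lo;
    else if (rr > hi) ex = rr - hi;
    if (ex != 0.0) {
      e += k * ex * ex;
      if (f) {
        double fr = -2.0 * k * ex / rr;
        add_pair_force(*f, i, j, fr * dx, fr * dy, fr * dz);
      }
    }
  }
  return e;
}

static double positional(const NumericMatrix& pr, const std::vector<double>& x,
                         std::vector<double>* f) {
  double e = 0.0;
  for (int r = 0; r < pr.nrow(); ++r) {
    int i = (int)pr(r, 0);
    double dx = x[3 * i] - pr(r, 1);
    double dy = x[3 * i + 1] - pr(r, 2);
    double dz = x[3 * i + 2] - pr(r, 3);
    double k = pr(r, 4);
    e += k * (dx * dx + dy * dy + dz * dz);
    if (f) {
      (*f)[3 * i] -= 2.0 * k * dx;
      (*f)[3 * i + 1] -= 2.0 * k * dy;
      (*f)[3 * i + 2] -= 2.0 * k * dz;
    }
  }
  return e;
}

// half-harmonic spherical wall on selected atoms
static double confinement(const Prep& p, const std::vector<double>& x,
                          std::vector<double>* f) {
  double e = 0.0;
  if (p.confine_k <= 0.0) return e;
  for (int a = 0; a < p.confine_atoms.size(); ++a) {
    int i = p.confine_atoms[a];
    double dx = x[3 * i] - p.confine_center[0];
    double dy = x[3 * i + 1] - p.confine_center[1];
    double dz = x[3 * i + 2] - p.confine_center[2];
    double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (rr > p.confine_radius) {
      double ex = rr - p.confine_radius;
      e += p.confine_k * ex * ex;
      if (f) {
        double fr = -2.0 * p.confine_k * ex / rr;
        (*f)[3 * i] += fr * dx;
        (*f)[3 * i + 1] += fr * dy;
        (*f)[3 * i + 2] += fr * dz;
      }
    }
  }
  return e;
}

// shared (state-independent) terms
static double shared_terms(const Prep& p, const std::vector<double>& x,
                           std::vector<double>* f) {
  double e = 0.0;
  e += buckingham(p.buck, x, f);
  e += flatbottom(p.restraints, x, f);
  e += positional(p.posres, x, f);
  e += confinement(p, x, f);
  return e;
}

static void eval_both(const Prep& p, const std::vector<double>& x,
                      double& e1, double& e2,
                      std::vector<double>* f1, std::vector<double>* f2) {
  if (f1) std::fill(f1->begin(), f1->end(), 0.0);
  if (f2) std::fill(f2->begin(), f2->end(), 0.0);
  e1 = nonbonded(p.pairs1, x, f1) + morse(p.bonds1, x, f1) +
       angles(p.angles1, x, f1);
  e2 = nonbonded(p.pairs2, x, f2) + morse(p.bonds2, x, f2) +
       angles(p.angles2, x, f2);
  // shared terms contribute identically to both states
  std::vector<double> fs;
  if (f1 || f2) fs.assign(3 * p.n, 0.0);
  double es = shared_terms(p, x, (f1 || f2) ? &fs : nullptr);
  e1 += es; e2 += es;
  if (f1) for (size_t k = 0; k < fs.size(); ++k) (*f1)[k] += fs[k];
  if (f2) for (size_t k = 0; k < fs.size(); ++k) (*f2)[k] += fs[k];
}

// [[Rcpp::export]]
List evb_eval_cpp(List prep, NumericMatrix coords, bool forces) {
  Prep p = unpack(prep);
  if (coords.nrow() != p.n) stop("coordinate count does not match topology");
  std::vector<double> x(3 * p.n);
  for (int i = 0; i < p.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  double e1, e2;
  if (!forces) {
    eval_both(p, x, e1, e2, nullptr, nullptr);
    return List::create(_["e1"] = e1, _["e2"] = e2);
  }
  std::vector<double> f1(3 * p.n), f2(3 * p.n);
  eval_both(p, x, e1, e2, &f1, &f2);
  NumericMatrix F1(p.n, 3), F2(p.n, 3);
  for (int i = 0; i < p.n; ++i)
    for (int d = 0; d < 3; ++d) {
      F1(i, d) = f1[3 * i + d];
      F2(i, d) = f2[3 * i + d];
    }
  return List::create(_["e1"] = e1, _["e2"] = e2,
                      _["f1"] = F1, _["f2"] = F2);
}

// BAOAB Langevin propagation on the mapping potential V = lam*E1 + (1-lam)*E2.
// Records (eps1, eps2) every `stride` production steps.  Gaussian noise comes
// from R's RNG, so trajectories are reproducible under set.seed().
// [[Rcpp::export]]
List evb_run_window_cpp(List prep, NumericMatrix coords, NumericMatrix vel,
                        double lam, int n_steps, int equil_steps, double dt,
                        double gamma_fs, double temperature, int stride,
                        LogicalVector mobile, int frame_stride,
                        double max_energy) {
  Prep p = unpack(prep);
  int n = p.n;
  if (coords.nrow() != n || vel.nrow() != n)
    stop("coordinate/velocity count does not match topology");
  std::vector<double> x(3 * n), v(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = coords(i, d);
      v[3 * i + d] = vel(i, d);
    }
  std::vector<double> f1(3 * n), f2(3 * n), fmap(3 * n);
  double e1, e2;
  double kT = KB * temperature;
  double c1 = (gamma_fs > 0.0) ? std::exp(-gamma_fs * dt) : 1.0;
  double c2 = (gamma_fs > 0.0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  int ndof_mobile = 0;
  for (int i = 0; i < n; ++i) if (mobile[i]) ndof_mobile += 3;

  RNGScope scope;

  auto forces = [&]() {
    eval_both(p, x, e1, e2, &f1, &f2);
    for (int k = 0; k < 3 * n; ++k)
      fmap[k] = lam * f1[k] + (1.0 - lam) * f2[k];
  };
  forces();

  int total = equil_steps + n_steps;
  int n_rec = (stride > 0) ? n_steps / stride : 0;
  NumericVector rec_e1(n_rec), rec_e2(n_rec);
  IntegerVector rec_step(n_rec);
  List frames;
  double tsum = 0.0;
  int tcount = 0, irec = 0;

  for (int s = 1; s <= total; ++s) {
    // B
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      double a = 0.5 * dt * F2A / p.mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += a * fmap[3 * i + d];
    }
    // A
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    }
    // O
    if (gamma_fs > 0.0) {
      for (int i = 0; i < n; ++i) {
        if (!mobile[i]) continue;
        double sd = std::sqrt(kT * F2A / p.mass[i]);
        for (int d = 0; d < 3; ++d)
          v[3 * i + d] = c1 * v[3 * i + d] + c2 * sd * norm_rand();
      }
    }
    // A
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    }
    // B
    forces();
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      double a = 0.5 * dt * F2A / p.mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += a * fmap[3 * i + d];
    }

    double vmap = lam * e1 + (1.0 - lam) * e2;
    if (!std::isfinite(vmap) || std::fabs(vmap) > max_energy)
      stop("energy divergence at step %d (V = %g kcal/mol)", s, vmap);

    if (s > equil_steps) {
      int sp = s - equil_steps;
      // kinetic temperature of mobile atoms
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        if (!mobile[i]) continue;
        double vv = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                    v[3 * i + 2] * v[3 * i + 2];
        ke += 0.5 * p.mass[i] * vv;
      }
      ke /= F2A;  // -> kcal/mol
      tsum += 2.0 * ke / (ndof_mobile * KB);
      ++tcount;
      if (stride > 0 && sp % stride == 0 && irec < n_rec) {
        rec_e1[irec] = e1;
        rec_e2[irec] = e2;
        rec_step[irec] = sp;
        ++irec;
      }
      if (frame_stride > 0 && sp % frame_stride == 0) {
        NumericMatrix fr(n, 3);
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d) fr(i, d) = x[3 * i + d];
        frames.push_back(fr);
      }
    }
    if (s % 500 == 0) checkUserInterrupt();
  }

  NumericMatrix Xout(n, 3), Vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      Xout(i, d) = x[3 * i + d];
      Vout(i, d) = v[3 * i + d];
    }
  return List::create(
    _["eps1"] = rec_e1, _["eps2"] = rec_e2, _["step"] = rec_step,
    _["mean_temperature"] = (tcount > 0) ? tsum / tcount : NA_REAL,
    _["coords"] = Xout, _["vel"] = Vout, _["frames"] = frames);
}
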