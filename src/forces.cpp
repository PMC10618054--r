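// Reduced-unit bead-chain force field: harmonic bonds, linear-placement
// angle term, saturating soft-core repulsion (chain-crossable), spherical
// confinement wall, and the pairwise Hi-C biasing potential.
// Units: length sigma, energy epsilon, time tau; masses fixed at 1.
// Hot loops use raw column pointers: these kernels sit inside the Langevin
// integrator and dominate the run time.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double WCA_CUT2 = 1.259921049894873;  // (2^(1/6))^2

// Smooth contact indicator f(r) = 1/2 (1 + tanh(eta (rc - r))).
// Its ensemble mean realizes the contact probability P_ij.
inline double indicator(double r, double rc, double eta) {
  return 0.5 * (1.0 + std::tanh(eta * (rc - r)));
}

struct FFParams {
  double bond_length, bond_stiffness, angle_stiffness;
  double softcore_strength, softcore_cap;
  double contact_cutoff, eta;
  double confinement_radius, wall_stiffness;
};

static FFParams unpack(const List& params) {
  FFParams p;
  p.bond_length        = as<double>(params["bond_length"]);
  p.bond_stiffness     = as<double>(params["bond_stiffness"]);
  p.angle_stiffness    = as<double>(params["angle_stiffness"]);
  p.softcore_strength  = as<double>(params["softcore_strength"]);
  p.softcore_cap       = as<double>(params["softcore_cap"]);
  p.contact_cutoff     = as<double>(params["contact_cutoff"]);
  p.eta                = as<double>(params["eta"]);
  p.confinement_radius = as<double>(params["confinement_radius"]);
  p.wall_stiffness     = as<double>(params["wall_stiffness"]);
  return p;
}

// Accumulate homopolymer energy and forces into F (Nx3, column-major).
// Returns energy components (bond, angle, softcore, wall).
static arma::vec homopolymer_ef(const arma::mat& X, const FFParams& p,
                                arma::mat& F) {
  const int n = X.n_rows;
  double e_bond = 0, e_angle = 0, e_sc = 0, e_wall = 0;
  const double *x = X.colptr(0), *y = X.colptr(1), *z = X.colptr(2);
  double *fx = F.colptr(0), *fy = F.colptr(1), *fz = F.colptr(2);

  // bonds: 1/2 k (|r_{i+1}-r_i| - r0)^2
  for (int i = 0; i + 1 < n; ++i) {
    double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
    double b = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dev = b - p.bond_length;
    e_bond += 0.5 * p.bond_stiffness * dev * dev;
    if (b > 1e-12) {
      double g = p.bond_stiffness * dev / b;
      fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
      fx[i + 1] -= g * dx; fy[i + 1] -= g * dy; fz[i + 1] -= g * dz;
    }
  }

  // angles: k_a (1 + cos theta), theta at bead i between a = r_{i-1}-r_i
  // and b = r_{i+1}-r_i; a straight chain (theta = pi) has zero energy.
  for (int i = 1; i + 1 < n; ++i) {
    double ax = x[i - 1] - x[i], ay = y[i - 1] - y[i], az = z[i - 1] - z[i];
    double bx = x[i + 1] - x[i], by = y[i + 1] - y[i], bz = z[i + 1] - z[i];
    double na2 = ax * ax + ay * ay + az * az;
    double nb2 = bx * bx + by * by + bz * bz;
    if (na2 < 1e-24 || nb2 < 1e-24) continue;
    double na = std::sqrt(na2), nb = std::sqrt(nb2);
    double inab = 1.0 / (na * nb);
    double ct = (ax * bx + ay * by + az * bz) * inab;
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
    e_angle += p.angle_stiffness * (1.0 + ct);
    double dax = bx * inab - ct * ax / na2;
    double day = by * inab - ct * ay / na2;
    double daz = bz * inab - ct * az / na2;
    double dbx = ax * inab - ct * bx / nb2;
    double dby = ay * inab - ct * by / nb2;
    double dbz = az * inab - ct * bz / nb2;
    double k = p.angle_stiffness;
    fx[i - 1] -= k * dax; fy[i - 1] -= k * day; fz[i - 1] -= k * daz;
    fx[i + 1] -= k * dbx; fy[i + 1] -= k * dby; fz[i + 1] -= k * dbz;
    fx[i] += k * (dax + dbx); fy[i] += k * (day + dby);
    fz[i] += k * (daz + dbz);
  }

  // soft-core: WCA repulsion passed through a saturating clamp
  // E = cap * tanh(WCA(r)/cap); bounded by cap per pair so chains can cross.
  if (p.softcore_strength > 0) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= WCA_CUT2) continue;
        if (r2 < 1e-18) r2 = 1e-18;  // capped kernel: no singularity
        double ir2 = 1.0 / r2;
        double ir6 = ir2 * ir2 * ir2;
        double wca = 4.0 * p.softcore_strength * (ir6 * ir6 - ir6)
                     + p.softcore_strength;
        double t = std::tanh(wca / p.softcore_cap);
        e_sc += p.softcore_cap * t;
        // force = -dE/dr * rhat; dE/dr = sech^2(wca/cap) * dwca/dr
        // dwca/dr / r = 4 eps (-12 ir6^2 + 6 ir6) / r^2
        double g = -(1.0 - t * t) * 4.0 * p.softcore_strength
                   * (-12.0 * ir6 * ir6 + 6.0 * ir6) * ir2;
        fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
        fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
      }
    }
  }

  // spherical confinement: half-harmonic wall outside R_c, centred at origin
  if (p.wall_stiffness > 0 && std::isfinite(p.confinement_radius)) {
    for (int i = 0; i < n; ++i) {
      double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
      if (r > p.confinement_radius) {
        double dev = r - p.confinement_radius;
        e_wall += 0.5 * p.wall_stiffness * dev * dev;
        double g = -p.wall_stiffness * dev / r;
        fx[i] += g * x[i]; fy[i] += g * y[i]; fz[i] += g * z[i];
      }
    }
  }

  arma::vec e(4);
  e(0) = e_bond; e(1) = e_angle; e(2) = e_sc; e(3) = e_wall;
  return e;
}

// Bias energy sum_{i<j} alpha_ij f(r_ij) and forces. The diagonal and
// first off-diagonals of alpha are zero by construction.
static double bias_ef(const arma::mat& X, const arma::mat& alpha,
                      double rc, double eta, arma::mat& F) {
  const int n = X.n_rows;
  double e = 0;
  const double *x = X.colptr(0), *y = X.colptr(1), *z = X.colptr(2);
  double *fx = F.colptr(0), *fy = F.colptr(1), *fz = F.colptr(2);
  // outside |r - rc| <= 8/eta the indicator is saturated to 16 digits:
  // the energy contribution is a or 0 and the force vanishes.
  double lo = rc - 8.0 / eta, hi = rc + 8.0 / eta;
  double lo2 = lo > 0 ? lo * lo : 0.0, hi2 = hi * hi;
  for (int j = 2; j < n; ++j) {
    const double *acol = alpha.colptr(j);
    for (int i = 0; i < j - 1; ++i) {
      double a = acol[i];
      if (a == 0.0) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= hi2) continue;          // f ~ 0
      if (r2 <= lo2) { e += a; continue; }  // f ~ 1, no force
      double r = std::sqrt(r2);
      if (r < 1e-9) r = 1e-9;
      double th = std::tanh(eta * (rc - r));
      e += a * 0.5 * (1.0 + th);
      // dE/dr = -a eta/2 sech^2; force = -dE/dr * rhat
      double g = a * 0.5 * eta * (1.0 - th * th) / r;
      fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
      fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
    }
  }
  return e;
}

// [[Rcpp::export(name = ".cc_homopolymer_ef")]]
List cc_homopolymer_ef(const arma::mat& X, const List& params) {
  FFParams p = unpack(params);
  arma::mat F(X.n_rows, 3, arma::fill::zeros);
  arma::vec e = homopolymer_ef(X, p, F);
  return List::create(
    _["energy"] = arma::accu(e),
    _["components"] = NumericVector::create(
      _["bond"] = e(0), _["angle"] = e(1),
      _["softcore"] = e(2), _["wall"] = e(3)),
    _["forces"] = F);
}

// [[Rcpp::export(name = ".cc_bias_ef")]]
List cc_bias_ef(const arma::mat& X, const arma::mat& alpha,
                double rc, double eta) {
  arma::mat F(X.n_rows, 3, arma::fill::zeros);
  double e = bias_ef(X, alpha, rc, eta, F);
  return List::create(_["energy"] = e, _["forces"] = F);
}

// [[Rcpp::export(name = ".cc_contact_matrix")]]
arma::mat cc_contact_matrix(const arma::mat& X, double rc, double eta) {
  const int n = X.n_rows;
  arma::mat P(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    P(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double f = indicator(arma::norm(X.row(i) - X.row(j)), rc, eta);
      P(i, j) = f; P(j, i) = f;
    }
  }
  return P;
}

// Mean indicator matrix over an ensemble stored as an N x 3 x M cube.
// [[Rcpp::export(name = ".cc_ensemble_contacts")]]
arma::mat cc_ensemble_contacts(const arma::cube& frames, double rc,
                               double eta) {
  const int n = frames.n_rows, m = frames.n_slices;
  arma::mat P(n, n, arma::fill::zeros);
  for (int k = 0; k < m; ++k) {
    const arma::mat& X = frames.slice(k);
    const double *x = X.colptr(0), *y = X.colptr(1), *z = X.colptr(2);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        P(i, j) += indicator(std::sqrt(dx * dx + dy * dy + dz * dz),
                             rc, eta);
      }
    }
  }
  P /= m;
  P = P + P.t();
  P.diag().ones();
  return P;
}

// BAOAB Langevin integrator with a linear temperature ramp.
// Noise comes from R's RNG so set.seed() controls reproducibility.
// [[Rcpp::export(name = ".cc_run_langevin")]]
List cc_run_langevin(const arma::mat& X0, const arma::mat& V0,
                     const List& params, const arma::mat& alpha,
                     bool use_bias, double dt, double gamma,
                     double T_start, double T_end, int ramp_steps,
                     int n_steps, int record_every) {
  FFParams p = unpack(params);
  const int n = X0.n_rows;
  arma::mat X = X0, V = V0;
  arma::mat F(n, 3, arma::fill::zeros);
  homopolymer_ef(X, p, F);
  if (use_bias) bias_ef(X, alpha, p.contact_cutoff, p.eta, F);

  int n_frames = n_steps / record_every + 1;
  arma::cube frames(n, 3, n_frames);
  arma::vec times(n_frames), temps(n_frames);
  frames.slice(0) = X;
  times(0) = 0.0; temps(0) = T_start;
  int fi = 1;

  const double c1 = std::exp(-gamma * dt);
  const double half_dt = 0.5 * dt;
  RNGScope scope;

  for (int s = 1; s <= n_steps; ++s) {
    double T = (ramp_steps > 0 && s < ramp_steps)
      ? T_start + (T_end - T_start) * (double)s / ramp_steps
      : T_end;
    double sigma_v = std::sqrt((1.0 - c1 * c1) * T);

    V += half_dt * F;                        // B
    X += half_dt * V;                        // A
    {                                        // O
      double *v = V.memptr();
      for (int q = 0; q < 3 * n; ++q)
        v[q] = c1 * v[q] + sigma_v * norm_rand();
    }
    X += half_dt * V;                        // A
    F.zeros();                               // B
    homopolymer_ef(X, p, F);
    if (use_bias) bias_ef(X, alpha, p.contact_cutoff, p.eta, F);
    if (!F.is_finite())
      stop("non-finite forces at step %d; simulation aborted", s);
    V += half_dt * F;

    if (s % record_every == 0) {
      frames.slice(fi) = X;
      times(fi) = s * dt;
      temps(fi) = T;
      ++fi;
    }
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["temperatures"] = temps,
                      _["final_velocities"] = V);
}

// Steepest-descent relaxation with displacement capping; used to regularize
// freshly grown random-walk chains before dynamics.
// [[Rcpp::export(name = ".cc_minimize")]]
arma::mat cc_minimize(const arma::mat& X0, const List& params,
                      int n_steps, double max_disp) {
  FFParams p = unpack(params);
  arma::mat X = X0;
  for (int s = 0; s < n_steps; ++s) {
    arma::mat F(X.n_rows, 3, arma::fill::zeros);
    homopolymer_ef(X, p, F);
    double fmax = std::sqrt(arma::max(arma::sum(arma::square(F), 1)));
    if (fmax < 1e-8) break;
    double scale = std::min(0.002, max_disp / fmax);
    X += scale * F;
  }
  return X;
}

// Optimal least-squares rotation (Kabsch) of X onto Y; both pre-centred.
static arma::mat kabsch_rotation(const arma::mat& X, const arma::mat& Y) {
  arma::mat H = X.t() * Y;  // 3x3
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, H);
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (arma::det(V * U.t()) < 0) ? -1.0 : 1.0;
  return V * D * U.t();
}

// [[Rcpp::export(name = ".cc_kabsch_rotate")]]
arma::mat cc_kabsch_rotate(const arma::mat& X, const arma::mat& Y) {
  arma::rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - cx, Yc = Y.each_row() - cy;
  arma::mat R = kabsch_rotation(Xc, Yc);
  return Xc * R.t();
}

// Pairwise minimum (Kabsch-aligned) RMSD over an ensemble cube.
// [[Rcpp::export(name = ".cc_pairwise_rmsd")]]
arma::mat cc_pairwise_rmsd(const arma::cube& frames) {
  const int m = frames.n_slices, n = frames.n_rows;
  arma::mat D(m, m, arma::fill::zeros);
  std::vector<arma::mat> centred(m);
  for (int k = 0; k < m; ++k) {
    arma::mat X = frames.slice(k);
    arma::rowvec c = arma::mean(X, 0);
    centred[k] = X.each_row() - c;
  }
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      arma::mat R = kabsch_rotation(centred[a], centred[b]);
      arma::mat diff = centred[a] * R.t() - centred[b];
      double rmsd = std::sqrt(arma::accu(arma::square(diff)) / n);
      D(a, b) = rmsd; D(b, a) = rmsd;
    }
  }
  return D;
}
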