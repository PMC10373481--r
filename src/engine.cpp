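// Langevin toy-dynamics engine (BAOAB splitting) with on-the-fly biasing of a
// collective variable by well-tempered metadynamics or OPES, plus quadratic
// wall potentials.  Units: kcal/mol, Angstrom, ps, amu, Kelvin.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double KB = 0.001987204259;  // kcal/mol/K
static const double KCAL = 418.4;         // kcal/mol/A/amu -> A/ps^2

// ---------------------------------------------------------------- dihedrals
static double dihedral_angle(const mat& X, int i, int j, int k, int l) {
  vec b1 = X.row(j).t() - X.row(i).t();
  vec b2 = X.row(k).t() - X.row(j).t();
  vec b3 = X.row(l).t() - X.row(k).t();
  vec m = cross(b1, b2);
  vec n = cross(b2, b3);
  double nm = norm(m), nn = norm(n), nb2 = norm(b2);
  if (nm < 1e-12 || nn < 1e-12 || nb2 < 1e-12)
    Rcpp::stop("degenerate (collinear) dihedral");
  double x = dot(m, n);
  double y = dot(cross(m, n), b2) / nb2;
  return std::atan2(y, x);
}

// Gradient of the dihedral angle with respect to the four atom positions.
static void dihedral_grad(const mat& X, int i, int j, int k, int l,
                          vec& gi, vec& gj, vec& gk, vec& gl) {
  vec b1 = X.row(j).t() - X.row(i).t();
  vec b2 = X.row(k).t() - X.row(j).t();
  vec b3 = X.row(l).t() - X.row(k).t();
  vec m = cross(b1, b2);
  vec n = cross(b2, b3);
  double m2 = dot(m, m), n2 = dot(n, n), nb2 = norm(b2);
  if (m2 < 1e-24 || n2 < 1e-24 || nb2 < 1e-12)
    Rcpp::stop("degenerate (collinear) dihedral");
  gi = -(nb2 / m2) * m;
  gl = (nb2 / n2) * n;
  double s = dot(b1, b2) / (nb2 * nb2);
  double t = dot(b3, b2) / (nb2 * nb2);
  gj = t * gl - (1.0 + s) * gi;
  gk = s * gi - (1.0 + t) * gl;
}

// [[Rcpp::export]]
double cpp_dihedral(const arma::mat& X, int i, int j, int k, int l) {
  return dihedral_angle(X, i - 1, j - 1, k - 1, l - 1);
}

// ------------------------------------------------------------ toy potential
// bonds: rows (i, j, r0, k)      [1-based indices from R]
// angles: rows (i, j, k, th0, kth)
// torsions: rows (i, j, k, l, type, p1, p2); type 1: quartic double well
//   U = p1 * ((phi/p2)^2 - 1)^2; type 2: harmonic about 0, U = 0.5 p1 phi^2.
struct ToyPot {
  mat bonds, angles, torsions;
};

static double toy_energy_force(const ToyPot& pot, const mat& X, mat& F) {
  F.zeros(X.n_rows, 3);
  double E = 0.0;
  for (uword b = 0; b < pot.bonds.n_rows; ++b) {
    int i = (int)pot.bonds(b, 0) - 1, j = (int)pot.bonds(b, 1) - 1;
    double r0 = pot.bonds(b, 2), k = pot.bonds(b, 3);
    vec d = X.row(i).t() - X.row(j).t();
    double r = norm(d);
    E += 0.5 * k * (r - r0) * (r - r0);
    vec f = -k * (r - r0) * d / r;
    F.row(i) += f.t();
    F.row(j) -= f.t();
  }
  for (uword a = 0; a < pot.angles.n_rows; ++a) {
    int i = (int)pot.angles(a, 0) - 1, j = (int)pot.angles(a, 1) - 1,
        k = (int)pot.angles(a, 2) - 1;
    double th0 = pot.angles(a, 3), kth = pot.angles(a, 4);
    vec rij = X.row(i).t() - X.row(j).t();
    vec rkj = X.row(k).t() - X.row(j).t();
    double nij = norm(rij), nkj = norm(rkj);
    double cth = dot(rij, rkj) / (nij * nkj);
    cth = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, cth));
    double th = std::acos(cth);
    double sth = std::sqrt(1.0 - cth * cth);
    E += 0.5 * kth * (th - th0) * (th - th0);
    vec gi = (cth * rij / nij - rkj / nkj) / (nij * sth);
    vec gk = (cth * rkj / nkj - rij / nij) / (nkj * sth);
    vec gj = -gi - gk;
    double dU = kth * (th - th0);
    F.row(i) -= (dU * gi).t();
    F.row(j) -= (dU * gj).t();
    F.row(k) -= (dU * gk).t();
  }
  for (uword t = 0; t < pot.torsions.n_rows; ++t) {
    int i = (int)pot.torsions(t, 0) - 1, j = (int)pot.torsions(t, 1) - 1,
        k = (int)pot.torsions(t, 2) - 1, l = (int)pot.torsions(t, 3) - 1;
    int type = (int)pot.torsions(t, 4);
    double p1 = pot.torsions(t, 5), p2 = pot.torsions(t, 6);
    double phi = dihedral_angle(X, i, j, k, l);
    double dU;
    if (type == 1) {
      double u = (phi / p2) * (phi / p2) - 1.0;
      E += p1 * u * u;
      dU = 4.0 * p1 * u * phi / (p2 * p2);
    } else {
      E += 0.5 * p1 * phi * phi;
      dU = p1 * phi;
    }
    vec gi, gj, gk, gl;
    dihedral_grad(X, i, j, k, l, gi, gj, gk, gl);
    F.row(i) -= (dU * gi).t();
    F.row(j) -= (dU * gj).t();
    F.row(k) -= (dU * gk).t();
    F.row(l) -= (dU * gl).t();
  }
  return E;
}

// [[Rcpp::export]]
Rcpp::List cpp_toy_energy_force(const arma::mat& X, const arma::mat& bonds,
                                const arma::mat& angles, const arma::mat& torsions) {
  ToyPot pot{bonds, angles, torsions};
  mat F;
  double E = toy_energy_force(pot, X, F);
  return Rcpp::List::create(Rcpp::Named("energy") = E, Rcpp::Named("force") = F);
}

// [[Rcpp::export]]
arma::mat cpp_minimize_toy(const arma::mat& X0, const arma::mat& bonds,
                           const arma::mat& angles, const arma::mat& torsions,
                           int n_iter, double step) {
  ToyPot pot{bonds, angles, torsions};
  mat X = X0, F;
  double E = toy_energy_force(pot, X, F);
  for (int it = 0; it < n_iter; ++it) {
    mat Xn = X + step * F;
    mat Fn;
    double En = toy_energy_force(pot, Xn, Fn);
    if (En < E) {
      X = Xn; F = Fn; E = En; step *= 1.2;
    } else {
      step *= 0.5;
      if (step < 1e-12) break;
    }
  }
  return X;
}

// ------------------------------------------------------------- bias on a CV
struct BiasGrid {
  double qmin, qmax, dq;
  int n;
  vec V;
  BiasGrid(double a, double b, int m) : qmin(a), qmax(b), n(m) {
    dq = (b - a) / (m - 1);
    V = zeros<vec>(m);
  }
  double interp(double q) const {
    if (q <= qmin) return V(0);
    if (q >= qmax) return V(n - 1);
    double u = (q - qmin) / dq;
    int i0 = (int)std::floor(u);
    double w = u - i0;
    return (1.0 - w) * V(i0) + w * V(i0 + 1);
  }
  double deriv(double q) const {
    return (interp(q + dq) - interp(q - dq)) / (2.0 * dq);
  }
};

struct WTBias {
  double h, sigma, kb_dT;  // kb_dT = kB * (gamma - 1) * T
  BiasGrid g;
  std::vector<double> hc, hh;  // hill centers and deposited heights
  WTBias(double h_, double sigma_, double gamma_, double T_, double qmin,
         double qmax, int ngrid)
      : h(h_), sigma(sigma_), kb_dT(KB * (gamma_ - 1.0) * T_), g(qmin, qmax, ngrid) {}
  void deposit(double Q) {
    double ht = h * std::exp(-g.interp(Q) / kb_dT);
    hc.push_back(Q);
    hh.push_back(ht);
    for (int i = 0; i < g.n; ++i) {
      double q = g.qmin + i * g.dq;
      g.V(i) += ht * std::exp(-(q - Q) * (q - Q) / (2.0 * sigma * sigma));
    }
  }
};

struct OPESBias {
  double sigma, gamma, kBT, deltaE, eps;
  double sumw = 0.0;
  std::vector<double> kc, kh;  // kernel centers and weights
  BiasGrid P;                  // unnormalized weighted kernel density
  OPESBias(double sigma_, double gamma_, double T_, double deltaE_, double qmin,
           double qmax, int ngrid)
      : sigma(sigma_), gamma(gamma_), kBT(KB * T_), deltaE(deltaE_),
        P(qmin, qmax, ngrid) {
    eps = std::exp(-deltaE / ((1.0 - 1.0 / gamma) * kBT));
  }
  double zint() const {
    // integral of the normalized density over the grid range
    return std::max(accu(P.V) * P.dq / std::max(sumw, 1e-300), 1e-300);
  }
  double bias(double q) const {
    if (sumw <= 0.0) return 0.0;
    double p = P.interp(q) / sumw;
    double v = (1.0 - 1.0 / gamma) * kBT *
               (std::log(p / zint() + eps) - std::log(eps));
    return std::min(std::max(v, 0.0), deltaE);
  }
  double deriv(double q) const {
    double d = P.dq;
    return (bias(q + d) - bias(q - d)) / (2.0 * d);
  }
  void add_to_grid(double c, double w, double sgn) {
    for (int i = 0; i < P.n; ++i) {
      double q = P.qmin + i * P.dq;
      P.V(i) += sgn * w * std::exp(-(q - c) * (q - c) / (2.0 * sigma * sigma));
    }
  }
  void deposit(double Q) {
    double w = std::exp(bias(Q) / kBT);
    // merge with the nearest kernel when closer than sigma / 2
    int nearest = -1;
    double best = sigma / 2.0;
    for (size_t i = 0; i < kc.size(); ++i) {
      double d = std::fabs(kc[i] - Q);
      if (d < best) { best = d; nearest = (int)i; }
    }
    if (nearest >= 0) {
      double h0 = kh[nearest], c0 = kc[nearest];
      double hn = h0 + w, cn = (h0 * c0 + w * Q) / hn;
      add_to_grid(c0, h0, -1.0);
      add_to_grid(cn, hn, +1.0);
      kc[nearest] = cn;
      kh[nearest] = hn;
    } else {
      kc.push_back(Q);
      kh.push_back(w);
      add_to_grid(Q, w, +1.0);
    }
    sumw += w;
  }
};

static double wall_energy(double Q, double lo, double hi, double kappa,
                          double& dV) {
  if (Q < lo) { dV = 2.0 * kappa * (Q - lo); return kappa * (Q - lo) * (Q - lo); }
  if (Q > hi) { dV = 2.0 * kappa * (Q - hi); return kappa * (Q - hi) * (Q - hi); }
  dV = 0.0;
  return 0.0;
}

// --------------------------------------------------------------- CV closure
// cv_type 0: signed dihedral of quad (1-based indices); 1: position-LDA.
struct CVDef {
  int type;
  ivec quad;
  mat mu, W;
  vec v;
  double fd_step;
  double value(const mat& X) const {
    if (type == 0)
      return dihedral_angle(X, quad(0) - 1, quad(1) - 1, quad(2) - 1, quad(3) - 1);
    mat Xc = X.each_row() - mean(X, 0);
    mat M = Xc.t() * W * mu;
    mat U, V2;
    vec s;
    svd(U, s, V2, M);
    mat D = eye(3, 3);
    if (det(U * V2.t()) < 0.0) D(2, 2) = -1.0;
    mat Xa = Xc * (U * D * V2.t());
    return dot(v, vectorise(Xa - mu));
  }
  void grad(const mat& X, mat& G) const {
    if (type == 0) {
      vec gi, gj, gk, gl;
      dihedral_grad(X, quad(0) - 1, quad(1) - 1, quad(2) - 1, quad(3) - 1, gi, gj,
                    gk, gl);
      G.zeros(X.n_rows, 3);
      G.row(quad(0) - 1) = gi.t();
      G.row(quad(1) - 1) = gj.t();
      G.row(quad(2) - 1) = gk.t();
      G.row(quad(3) - 1) = gl.t();
      return;
    }
    G.set_size(X.n_rows, 3);
    mat Xp = X;
    for (uword j = 0; j < 3; ++j) {
      for (uword i = 0; i < X.n_rows; ++i) {
        double orig = Xp(i, j);
        Xp(i, j) = orig + fd_step;
        double lp = value(Xp);
        Xp(i, j) = orig - fd_step;
        double lm = value(Xp);
        Xp(i, j) = orig;
        G(i, j) = (lp - lm) / (2.0 * fd_step);
      }
    }
  }
};

// ------------------------------------------------------------------ engine
// [[Rcpp::export]]
Rcpp::List cpp_run_toy(const arma::mat& X0, const arma::mat& bonds,
                       const arma::mat& angles, const arma::mat& torsions,
                       const arma::vec& masses, double dt, double friction,
                       double temperature, int n_steps, int seed, int stride,
                       int bias_type, Rcpp::List bias_params, int cv_type,
                       Rcpp::List cv_params, bool use_walls, double wall_lo,
                       double wall_hi, double wall_kappa,
                       const arma::ivec& handed_quad) {
  ToyPot pot{bonds, angles, torsions};
  const uword N = X0.n_rows;
  CVDef cv;
  cv.type = cv_type;
  if (cv_type == 0) {
    cv.quad = Rcpp::as<arma::ivec>(cv_params["quad"]);
  } else {
    cv.mu = Rcpp::as<arma::mat>(cv_params["mean"]);
    cv.W = Rcpp::as<arma::mat>(cv_params["precision"]);
    cv.v = Rcpp::as<arma::vec>(cv_params["v"]);
    cv.fd_step = Rcpp::as<double>(cv_params["fd_step"]);
  }
  bool need_cv_force = (bias_type != 0) || use_walls;

  std::unique_ptr<WTBias> wt;
  std::unique_ptr<OPESBias> op;
  int pace = 0;
  if (bias_type == 1) {
    wt.reset(new WTBias(Rcpp::as<double>(bias_params["height"]),
                        Rcpp::as<double>(bias_params["sigma"]),
                        Rcpp::as<double>(bias_params["gamma"]), temperature,
                        Rcpp::as<double>(bias_params["qmin"]),
                        Rcpp::as<double>(bias_params["qmax"]),
                        Rcpp::as<int>(bias_params["ngrid"])));
    pace = Rcpp::as<int>(bias_params["pace"]);
  } else if (bias_type == 2) {
    op.reset(new OPESBias(Rcpp::as<double>(bias_params["sigma"]),
                          Rcpp::as<double>(bias_params["gamma"]), temperature,
                          Rcpp::as<double>(bias_params["deltaE"]),
                          Rcpp::as<double>(bias_params["qmin"]),
                          Rcpp::as<double>(bias_params["qmax"]),
                          Rcpp::as<int>(bias_params["ngrid"])));
    pace = Rcpp::as<int>(bias_params["pace"]);
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  mat X = X0;
  mat Vel(N, 3);
  double kBT = KB * temperature;
  for (uword i = 0; i < N; ++i)
    for (uword j = 0; j < 3; ++j)
      Vel(i, j) = std::sqrt(kBT * KCAL / masses(i)) * gauss(rng);

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);

  int n_rec = n_steps / stride;
  cube frames(N, 3, n_rec);
  vec cv_series(n_rec), bias_series(n_rec), wall_series(n_rec),
      energy_series(n_rec), handed_series(n_rec), time_series(n_rec);

  mat F, Gcv(N, 3);
  double E = toy_energy_force(pot, X, F);
  double max_force = 0.0;
  bool crashed = false;
  int crash_step = -1;

  auto add_bias_force = [&](const mat& Xc, mat& Fout, double& Ebias,
                            double& Ewall, double& Q) {
    Ebias = 0.0;
    Ewall = 0.0;
    if (!need_cv_force) return;
    Q = cv.value(Xc);
    double dV = 0.0;
    if (wt) { Ebias = wt->g.interp(Q); dV += wt->g.deriv(Q); }
    if (op) { Ebias = op->bias(Q); dV += op->deriv(Q); }
    if (use_walls) {
      double dW;
      Ewall = wall_energy(Q, wall_lo, wall_hi, wall_kappa, dW);
      dV += dW;
    }
    if (dV != 0.0) {
      cv.grad(Xc, Gcv);
      Fout -= dV * Gcv;
    }
  };

  double Ebias = 0.0, Ewall = 0.0, Q = 0.0;
  add_bias_force(X, F, Ebias, Ewall, Q);

  for (int step = 0; step < n_steps && !crashed; ++step) {
    for (uword i = 0; i < N; ++i) {
      double a = 0.5 * dt * KCAL / masses(i);
      Vel.row(i) += a * F.row(i);
    }
    X += 0.5 * dt * Vel;
    if (friction > 0) {
      for (uword i = 0; i < N; ++i) {
        double s = std::sqrt(kBT * KCAL / masses(i));
        for (uword j = 0; j < 3; ++j)
          Vel(i, j) = c1 * Vel(i, j) + c2 * s * gauss(rng);
      }
    }
    X += 0.5 * dt * Vel;
    E = toy_energy_force(pot, X, F);
    add_bias_force(X, F, Ebias, Ewall, Q);
    double fmax = abs(F).max();
    if (!F.is_finite() || !X.is_finite()) {
      crashed = true;
      crash_step = step;
      break;
    }
    if (fmax > max_force) max_force = fmax;
    for (uword i = 0; i < N; ++i) {
      double a = 0.5 * dt * KCAL / masses(i);
      Vel.row(i) += a * F.row(i);
    }
    if (pace > 0 && ((step + 1) % pace == 0)) {
      double Qd = need_cv_force ? Q : cv.value(X);
      if (wt) wt->deposit(Qd);
      if (op) op->deposit(Qd);
    }
    if ((step + 1) % stride == 0) {
      int r = (step + 1) / stride - 1;
      frames.slice(r) = X;
      double Qr = need_cv_force ? Q : cv.value(X);
      cv_series(r) = Qr;
      bias_series(r) = Ebias;
      wall_series(r) = Ewall;
      double ke = 0.0;
      for (uword i = 0; i < N; ++i)
        ke += 0.5 * masses(i) * dot(Vel.row(i), Vel.row(i)) / KCAL;
      energy_series(r) = E + ke;
      handed_series(r) = dihedral_angle(X, handed_quad(0) - 1, handed_quad(1) - 1,
                                        handed_quad(2) - 1, handed_quad(3) - 1);
      time_series(r) = (step + 1) * dt;
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("frames") = frames, Rcpp::Named("time") = time_series,
      Rcpp::Named("cv") = cv_series, Rcpp::Named("bias") = bias_series,
      Rcpp::Named("wall") = wall_series, Rcpp::Named("energy") = energy_series,
      Rcpp::Named("handedness") = handed_series,
      Rcpp::Named("max_force") = max_force, Rcpp::Named("crashed") = crashed,
      Rcpp::Named("crash_step") = crash_step);
  if (wt) {
    out["hill_centers"] = wt->hc;
    out["hill_heights"] = wt->hh;
    out["grid_q"] = regspace<vec>(0, wt->g.n - 1) * wt->g.dq + wt->g.qmin;
    out["grid_bias"] = wt->g.V;
  }
  if (op) {
    vec q = regspace<vec>(0, op->P.n - 1) * op->P.dq + op->P.qmin;
    vec vb(q.n_elem);
    for (uword i = 0; i < q.n_elem; ++i) vb(i) = op->bias(q(i));
    out["kernel_centers"] = op->kc;
    out["kernel_weights"] = op->kh;
    out["grid_q"] = q;
    out["grid_bias"] = vb;
  }
  return out;
}

// 1D double-well engine: one coordinate x with U = a ((x/x0)^2 - 1)^2,
// biased directly on Q = x.  Used for bias-method validation.
// [[Rcpp::export]]
Rcpp::List cpp_run_dw1d(double x_init, double a, double x0, double mass,
                        double dt, double friction, double temperature,
                        int n_steps, int seed, int stride, int bias_type,
                        Rcpp::List bias_params) {
  std::unique_ptr<WTBias> wt;
  std::unique_ptr<OPESBias> op;
  int pace = 0;
  if (bias_type == 1) {
    wt.reset(new WTBias(Rcpp::as<double>(bias_params["height"]),
                        Rcpp::as<double>(bias_params["sigma"]),
                        Rcpp::as<double>(bias_params["gamma"]), temperature,
                        Rcpp::as<double>(bias_params["qmin"]),
                        Rcpp::as<double>(bias_params["qmax"]),
                        Rcpp::as<int>(bias_params["ngrid"])));
    pace = Rcpp::as<int>(bias_params["pace"]);
  } else if (bias_type == 2) {
    op.reset(new OPESBias(Rcpp::as<double>(bias_params["sigma"]),
                          Rcpp::as<double>(bias_params["gamma"]), temperature,
                          Rcpp::as<double>(bias_params["deltaE"]),
                          Rcpp::as<double>(bias_params["qmin"]),
                          Rcpp::as<double>(bias_params["qmax"]),
                          Rcpp::as<int>(bias_params["ngrid"])));
    pace = Rcpp::as<int>(bias_params["pace"]);
  }
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double kBT = KB * temperature;
  double x = x_init;
  double v = std::sqrt(kBT * KCAL / mass) * gauss(rng);
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  auto force = [&](double xx) {
    // x0 == 0 selects the harmonic limit U = a x^2
    double f = (x0 <= 0.0)
                   ? -2.0 * a * xx
                   : -a * 4.0 * xx * ((xx / x0) * (xx / x0) - 1.0) / (x0 * x0);
    if (wt) f -= wt->g.deriv(xx);
    if (op) f -= op->deriv(xx);
    return f;
  };
  int n_rec = n_steps / stride;
  vec xs(n_rec), vb(n_rec), ts(n_rec);
  double f = force(x);
  for (int step = 0; step < n_steps; ++step) {
    v += 0.5 * dt * KCAL / mass * f;
    x += 0.5 * dt * v;
    v = c1 * v + c2 * std::sqrt(kBT * KCAL / mass) * gauss(rng);
    x += 0.5 * dt * v;
    f = force(x);
    v += 0.5 * dt * KCAL / mass * f;
    if (pace > 0 && ((step + 1) % pace == 0)) {
      if (wt) wt->deposit(x);
      if (op) op->deposit(x);
    }
    if ((step + 1) % stride == 0) {
      int r = (step + 1) / stride - 1;
      xs(r) = x;
      vb(r) = wt ? wt->g.interp(x) : (op ? op->bias(x) : 0.0);
      ts(r) = (step + 1) * dt;
    }
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("x") = xs,
                                      Rcpp::Named("bias") = vb,
                                      Rcpp::Named("time") = ts);
  if (wt) {
    out["hill_centers"] = wt->hc;
    out["hill_heights"] = wt->hh;
    out["grid_q"] = regspace<vec>(0, wt->g.n - 1) * wt->g.dq + wt->g.qmin;
    out["grid_bias"] = wt->g.V;
  }
  if (op) {
    vec q = regspace<vec>(0, op->P.n - 1) * op->P.dq + op->P.qmin;
    vec vv(q.n_elem);
    for (uword i = 0; i < q.n_elem; ++i) vv(i) = op->bias(q(i));
    out["grid_q"] = q;
    out["grid_bias"] = vv;
    out["kernel_centers"] = op->kc;
    out["kernel_weights"] = op->kh;
  }
  return out;
}
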