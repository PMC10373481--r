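// Size-and-shape-space alignment under a Kronecker (Sigma_N x I3) covariance:
// Mahalanobis-optimal rigid-body transforms, iterative mean/covariance
// estimation, and on-the-fly evaluation of the position-LDA coordinate.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat center_rows(const mat& X) {
  rowvec c = mean(X, 0);
  return X.each_row() - c;
}

// Proper rotation R maximizing tr(R^T M); applied to positions as X * R.
static mat rot_from_M(const mat& M) {
  mat U, V;
  vec s;
  if (!svd(U, s, V, M)) Rcpp::stop("SVD failure in rotation solve");
  mat D = eye(3, 3);
  if (det(U * V.t()) < 0.0) D(2, 2) = -1.0;
  return U * D * V.t();
}

// Rank-truncated pseudo-inverse of a symmetric PSD matrix; eigenvalues below
// tau * lambda_max are dropped.  Returns precision, rank, eigvals.
static void pinv_trunc(const mat& S, double tau, mat& W, int& rank, vec& evals) {
  mat Ssym = 0.5 * (S + S.t());
  mat V;
  if (!eig_sym(evals, V, Ssym)) Rcpp::stop("eigendecomposition failure");
  double lmax = evals.max();
  rank = 0;
  vec inv_e = zeros<vec>(evals.n_elem);
  if (lmax > 0) {
    double thr = tau * lmax;
    for (uword i = 0; i < evals.n_elem; ++i) {
      if (evals(i) > thr) {
        inv_e(i) = 1.0 / evals(i);
        rank++;
      }
    }
  }
  W = V * diagmat(inv_e) * V.t();
}

// [[Rcpp::export]]
Rcpp::List cpp_pinv_trunc(const arma::mat& S, double tau) {
  mat W;
  int rank;
  vec evals;
  pinv_trunc(S, tau, W, rank, evals);
  return Rcpp::List::create(Rcpp::Named("precision") = W,
                            Rcpp::Named("rank") = rank,
                            Rcpp::Named("evals") = evals);
}

// [[Rcpp::export]]
arma::mat cpp_kabsch(const arma::mat& X, const arma::mat& mu, const arma::mat& W) {
  // X assumed centered; minimizes tr[(XR - mu)^T W (XR - mu)] over SO(3).
  mat M = X.t() * W * mu;
  return rot_from_M(M);
}

// [[Rcpp::export]]
double cpp_mahal_sq(const arma::mat& X, const arma::mat& mu, const arma::mat& W) {
  mat D = X - mu;
  return accu(D % (W * D));
}

// [[Rcpp::export]]
arma::mat cpp_align_frame(const arma::mat& X, const arma::mat& mu, const arma::mat& W) {
  mat Xc = center_rows(X);
  return Xc * cpp_kabsch(Xc, mu, W);
}

// [[Rcpp::export]]
arma::cube cpp_align_traj(const arma::cube& T, const arma::mat& mu, const arma::mat& W) {
  cube out(size(T));
  for (uword f = 0; f < T.n_slices; ++f) {
    out.slice(f) = cpp_align_frame(T.slice(f), mu, W);
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_mahal_traj(const arma::cube& T, const arma::mat& mu, const arma::mat& W) {
  vec d(T.n_slices);
  for (uword f = 0; f < T.n_slices; ++f) {
    d(f) = cpp_mahal_sq(cpp_align_frame(T.slice(f), mu, W), mu, W);
  }
  return d;
}

// Alternating estimation of mean and particle covariance in size-and-shape
// space: align all frames to the current (mu, Sigma_N^+), re-average, repeat.
// Sigma_N uses the per-Cartesian-dimension average convention (divide by 3n).
// [[Rcpp::export]]
Rcpp::List cpp_iterative_mean_cov(const arma::cube& T, double tol, int max_iter,
                                  double tau) {
  const uword n = T.n_slices;
  const uword N = T.n_rows;
  mat mu = center_rows(T.slice(0));
  mat W = eye(N, N);
  mat cov = eye(N, N);
  int rank = N;
  vec evals;
  std::vector<double> objective;
  double delta = datum::inf;
  int iter = 0;
  cube aligned(size(T));
  for (iter = 1; iter <= max_iter; ++iter) {
    for (uword f = 0; f < n; ++f) {
      aligned.slice(f) = cpp_align_frame(T.slice(f), mu, W);
    }
    mat mu_new = zeros(N, 3);
    for (uword f = 0; f < n; ++f) mu_new += aligned.slice(f);
    mu_new /= (double)n;
    mu_new = center_rows(mu_new);
    mat S = zeros(N, N);
    for (uword f = 0; f < n; ++f) {
      mat D = aligned.slice(f) - mu_new;
      S += D * D.t();  // sums the three Cartesian dimensions
    }
    S /= (3.0 * n);
    mat W_new;
    pinv_trunc(S, tau, W_new, rank, evals);
    if (rank == 0) W_new = eye(N, N);  // zero-variance degenerate trajectory
    // negative log-likelihood per frame (up to constants): mean Mahalanobis^2
    // + 3 * logdet on the retained subspace
    double md = 0.0;
    for (uword f = 0; f < n; ++f) md += cpp_mahal_sq(aligned.slice(f), mu_new, W_new);
    double logdet = 0.0;
    if (rank > 0) {
      double thr = tau * evals.max();
      for (uword i = 0; i < evals.n_elem; ++i)
        if (evals(i) > thr) logdet += std::log(evals(i));
    }
    objective.push_back(md / n + 3.0 * logdet);
    delta = abs(mu_new - mu).max();
    mu = mu_new;
    cov = S;
    W = W_new;
    if (delta < tol) break;
  }
  bool converged = delta < tol;
  // final alignment pass against the converged reference
  for (uword f = 0; f < n; ++f) aligned.slice(f) = cpp_align_frame(T.slice(f), mu, W);
  return Rcpp::List::create(
      Rcpp::Named("mean") = mu, Rcpp::Named("cov") = cov,
      Rcpp::Named("precision") = W, Rcpp::Named("rank") = rank,
      Rcpp::Named("aligned") = aligned, Rcpp::Named("iterations") = std::min(iter, max_iter),
      Rcpp::Named("converged") = converged, Rcpp::Named("delta") = delta,
      Rcpp::Named("objective") = objective);
}

// Value of the LDA coordinate for a raw (unaligned) frame: center, rotate to
// the model reference with the Mahalanobis-optimal rotation, then dot with v.
// v uses column-major stacking of the N x 3 frame (all x, all y, all z).
// [[Rcpp::export]]
double cpp_cv(const arma::mat& X, const arma::mat& mu, const arma::mat& W,
              const arma::vec& v) {
  mat Xa = cpp_align_frame(X, mu, W);
  return dot(v, vectorise(Xa - mu));
}

// [[Rcpp::export]]
arma::vec cpp_cv_many(const arma::cube& T, const arma::mat& mu, const arma::mat& W,
                      const arma::vec& v) {
  vec l(T.n_slices);
  for (uword f = 0; f < T.n_slices; ++f) l(f) = cpp_cv(T.slice(f), mu, W, v);
  return l;
}

// Central-difference gradient of the coordinate with respect to the raw
// coordinates, including the implicit dependence of the optimal rotation.
// [[Rcpp::export]]
arma::mat cpp_cv_grad(const arma::mat& X, const arma::mat& mu, const arma::mat& W,
                      const arma::vec& v, double h) {
  const uword N = X.n_rows;
  mat G(N, 3);
  mat Xp = X;
  for (uword j = 0; j < 3; ++j) {
    for (uword i = 0; i < N; ++i) {
      double orig = Xp(i, j);
      Xp(i, j) = orig + h;
      double lp = cpp_cv(Xp, mu, W, v);
      Xp(i, j) = orig - h;
      double lm = cpp_cv(Xp, mu, W, v);
      Xp(i, j) = orig;
      G(i, j) = (lp - lm) / (2.0 * h);
    }
  }
  return G;
}
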