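// Data-augmented MCMC kernels for the multivariate latent Student-t
// regression model, plus a Genz-type randomized-QMC orthant integrator
// for the location-shifted multivariate t distribution.
//
// Model: Z_i | phi_i ~ N(mu_i, (delta^2/phi_i) R), phi_i ~ Gamma(nu/2, nu/2)
// so that marginally Z_i ~ St_p(mu_i, delta^2 R, nu); y_ij = 1(Z_ij > 0).
// All random draws go through R's RNG so chains are reproducible from
// set.seed() on the R side; the orthant integrator uses its own small
// counter-based generator seeded per call so it never disturbs the chain
// RNG stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

// ---------------------------------------------------------------------------
// one-sided truncated standard normal, truncated to [a, Inf)
// rejection from the untruncated normal when a is small, Robert (1995)
// exponential-proposal rejection in the upper tail
static double rtnorm_lower(double a) {
  if (a < 0.45) {
    double z;
    do {
      z = norm_rand();
    } while (z < a);
    return z;
  }
  const double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a - std::log(unif_rand()) / alpha;
    double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    if (unif_rand() <= rho) return z;
  }
}

// N(m, sd^2) truncated to (0, Inf) if pos, else to (-Inf, 0]
static double rtnorm_sign(double m, double sd, bool pos) {
  if (pos) {
    return m + sd * rtnorm_lower(-m / sd);
  }
  return m - sd * rtnorm_lower(m / sd);
}

// ---------------------------------------------------------------------------
// free off-diagonal ordering: row-major upper triangle
// p=4: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
static void fill_corr(const vec& r, int p, mat& R) {
  R.eye(p, p);
  int k = 0;
  for (int i = 0; i < p - 1; ++i)
    for (int j = i + 1; j < p; ++j) {
      R(i, j) = r(k);
      R(j, i) = r(k);
      ++k;
    }
}

static vec corr_free(const mat& R) {
  int p = R.n_rows;
  vec r(p * (p - 1) / 2);
  int k = 0;
  for (int i = 0; i < p - 1; ++i)
    for (int j = i + 1; j < p; ++j) r(k++) = R(i, j);
  return r;
}

// log of prod_i N(z_i | mu_i, (delta^2/phi_i) R) up to terms not involving R
// ok=false if R is not positive definite
static double loglik_R(const mat& D, const vec& phi, const mat& R,
                       double delta_sq, bool& ok) {
  mat U;
  ok = arma::chol(U, R);
  if (!ok) return -arma::datum::inf;
  double ldet = 2.0 * arma::sum(arma::log(U.diag()));
  // quad_i = d_i' R^{-1} d_i with R = U'U:  solve L w = d, quad = ||w||^2
  mat W = arma::solve(arma::trimatl(U.t()), D.t());
  arma::rowvec quad = arma::sum(W % W, 0);
  double q = arma::dot(phi, quad.t());
  return -0.5 * D.n_rows * ldet - 0.5 * q / delta_sq;
}

// ---------------------------------------------------------------------------
// single-site conditional updates (exported individually so the R-level
// operations exercise exactly the kernels run_chain uses)

// [[Rcpp::export]]
arma::vec cpp_update_phi(const arma::mat& Z, const arma::mat& Mu,
                         const arma::mat& R, double delta_sq, double nu) {
  int n = Z.n_rows, p = Z.n_cols;
  mat Rinv = arma::inv_sympd(R);
  mat D = Z - Mu;
  vec phi(n);
  double shape = 0.5 * (nu + p);
  for (int i = 0; i < n; ++i) {
    double q = arma::as_scalar(D.row(i) * Rinv * D.row(i).t()) / delta_sq;
    phi(i) = R::rgamma(shape, 2.0 / (nu + q));
  }
  return phi;
}

// [[Rcpp::export]]
arma::mat cpp_update_Z(const arma::mat& Z0, const arma::imat& Y,
                       const arma::mat& Mu, const arma::mat& R,
                       const arma::vec& phi, double delta_sq) {
  mat Z = Z0;
  int n = Z.n_rows, p = Z.n_cols;
  mat Om = arma::inv_sympd(R);
  for (int i = 0; i < n; ++i) {
    double s2 = delta_sq / phi(i);
    for (int j = 0; j < p; ++j) {
      double dot = 0.0;
      for (int k = 0; k < p; ++k)
        if (k != j) dot += Om(j, k) * (Z(i, k) - Mu(i, k));
      double cmean = Mu(i, j) - dot / Om(j, j);
      double csd = std::sqrt(s2 / Om(j, j));
      Z(i, j) = rtnorm_sign(cmean, csd, Y(i, j) == 1);
    }
  }
  return Z;
}

// stacked coefficient vector b = vec(B) with B p x d (outcome index fastest);
// prior: independent N(0, 1/prior_prec_k) per element
// [[Rcpp::export]]
arma::vec cpp_update_beta(const arma::mat& Z, const arma::mat& X,
                          const arma::vec& phi, const arma::mat& R,
                          double delta_sq, const arma::vec& prior_prec) {
  int d = X.n_cols, p = Z.n_cols;
  mat Rinv = arma::inv_sympd(R);
  mat Xw = X.each_col() % phi;
  mat XtWX = X.t() * Xw;                       // d x d
  mat P = arma::kron(XtWX, Rinv) / delta_sq;   // pd x pd
  P.diag() += prior_prec;
  mat M = Z.t() * Xw;                          // p x d
  vec lin = arma::vectorise(Rinv * M) / delta_sq;
  mat U = arma::chol(P);                       // P = U'U
  vec m = arma::solve(arma::trimatu(U),
                      arma::solve(arma::trimatl(U.t()), lin));
  vec zdraw(p * d);
  for (int k = 0; k < p * d; ++k) zdraw(k) = norm_rand();
  return m + arma::solve(arma::trimatu(U), zdraw);
}

// random-walk Metropolis on the free off-diagonals; flat prior over the
// correlation-matrix space cancels; non-PD proposals are rejections
// [[Rcpp::export]]
Rcpp::List cpp_update_R(const arma::mat& Z, const arma::mat& Mu,
                        const arma::vec& phi, const arma::vec& r,
                        double delta_sq, double proposal_scale) {
  int p = Z.n_cols;
  int nf = r.n_elem;
  mat D = Z - Mu;
  mat Rcur;
  fill_corr(r, p, Rcur);
  bool ok;
  double ll_cur = loglik_R(D, phi, Rcur, delta_sq, ok);
  vec rstar = r;
  for (int k = 0; k < nf; ++k) rstar(k) += proposal_scale * norm_rand();
  bool valid = true;
  for (int k = 0; k < nf; ++k)
    if (std::abs(rstar(k)) >= 1.0) valid = false;
  bool accepted = false;
  if (valid) {
    mat Rstar;
    fill_corr(rstar, p, Rstar);
    double ll_star = loglik_R(D, phi, Rstar, delta_sq, ok);
    if (ok && std::log(unif_rand()) < ll_star - ll_cur) accepted = true;
  }
  return List::create(_["r"] = accepted ? rstar : r,
                      _["accepted"] = accepted);
}

// ---------------------------------------------------------------------------
// full chain: sweep order phi -> Z -> beta -> R; Robbins-Monro adaptation of
// the proposal scale toward target_accept during burn-in only

// [[Rcpp::export]]
Rcpp::List cpp_run_chain(const arma::imat& Y, const arma::mat& X, double nu,
                         double delta_sq, const arma::vec& prior_prec,
                         int n_iter, int n_burn, int thin,
                         double proposal_scale, bool adapt,
                         double target_accept) {
  int n = Y.n_rows, p = Y.n_cols, d = X.n_cols;
  int nf = p * (p - 1) / 2;
  int m = (n_iter - n_burn - 1) / thin + 1;

  mat B(p, d, arma::fill::zeros);
  mat Mu(n, p, arma::fill::zeros);
  mat R = arma::eye(p, p);
  vec r(nf, arma::fill::zeros);
  vec phi(n, arma::fill::ones);
  double delta = std::sqrt(delta_sq);
  mat Z(n, p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) Z(i, j) = Y(i, j) == 1 ? delta / 2 : -delta / 2;

  mat beta_draws(m, p * d);
  mat r_draws(m, nf);
  int stored = 0;
  long accept_post = 0, post_iters = 0;
  double ls = std::log(proposal_scale > 0 ? proposal_scale : 1.0);

  for (int it = 1; it <= n_iter; ++it) {
    phi = cpp_update_phi(Z, Mu, R, delta_sq, nu);
    Z = cpp_update_Z(Z, Y, Mu, R, phi, delta_sq);
    vec b = cpp_update_beta(Z, X, phi, R, delta_sq, prior_prec);
    B = arma::reshape(b, p, d);
    Mu = X * B.t();
    bool acc = true;  // proposal_scale == 0: chain never moves, counted accepted
    if (nf > 0 && proposal_scale > 0) {
      List up = cpp_update_R(Z, Mu, phi, r, delta_sq, proposal_scale);
      r = as<vec>(up["r"]);
      acc = as<bool>(up["accepted"]);
      fill_corr(r, p, R);
    }
    if (adapt && it <= n_burn && proposal_scale > 0) {
      double gamma = 2.0 / std::pow((double)it, 0.6);
      ls += gamma * ((acc ? 1.0 : 0.0) - target_accept);
      proposal_scale = std::exp(ls);
    }
    if (it > n_burn) {
      ++post_iters;
      accept_post += acc ? 1 : 0;
      if ((it - n_burn - 1) % thin == 0 && stored < m) {
        beta_draws.row(stored) = b.t();
        if (nf > 0) r_draws.row(stored) = r.t();
        ++stored;
      }
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["beta"] = beta_draws, _["r"] = r_draws, _["n_retained"] = stored,
      _["acceptance_rate"] = post_iters > 0 ? (double)accept_post / post_iters
                                            : NA_REAL,
      _["proposal_scale_final"] = proposal_scale);
}

// ---------------------------------------------------------------------------
// successive-conditional simulation (sample data from the model at the
// current parameters, then apply every posterior update): under a correct
// sampler the marginal law of (beta, R) is exactly the prior

// [[Rcpp::export]]
Rcpp::List cpp_sc_chain(const arma::mat& X, double nu, double delta_sq,
                        const arma::vec& prior_prec, int n_sweeps,
                        double proposal_scale) {
  int n = X.n_rows, d = X.n_cols;
  int p = prior_prec.n_elem / d;
  int nf = p * (p - 1) / 2;

  // initial parameters drawn from the prior
  vec b(p * d);
  for (int k = 0; k < p * d; ++k)
    b(k) = norm_rand() / std::sqrt(prior_prec(k));
  mat B = arma::reshape(b, p, d);
  vec r(nf);
  mat R(p, p);
  for (;;) {  // rejection draw from the flat prior on the correlation space
    for (int k = 0; k < nf; ++k) r(k) = 2.0 * unif_rand() - 1.0;
    fill_corr(r, p, R);
    mat U;
    if (arma::chol(U, R)) break;
  }

  mat draws(n_sweeps, p * d + nf);
  mat Mu = X * B.t();
  for (int s = 0; s < n_sweeps; ++s) {
    // forward-simulate (phi, Z, y) from the model at the current parameters
    vec phi(n);
    arma::imat Y(n, p);
    mat Z(n, p);
    mat L = arma::chol(R, "lower");
    for (int i = 0; i < n; ++i) {
      phi(i) = R::rgamma(nu / 2.0, 2.0 / nu);
      vec e(p);
      for (int j = 0; j < p; ++j) e(j) = norm_rand();
      vec z = Mu.row(i).t() + std::sqrt(delta_sq / phi(i)) * (L * e);
      for (int j = 0; j < p; ++j) {
        Z(i, j) = z(j);
        Y(i, j) = z(j) > 0 ? 1 : 0;
      }
    }
    // posterior transition kernel given the simulated data
    phi = cpp_update_phi(Z, Mu, R, delta_sq, nu);
    Z = cpp_update_Z(Z, Y, Mu, R, phi, delta_sq);
    b = cpp_update_beta(Z, X, phi, R, delta_sq, prior_prec);
    B = arma::reshape(b, p, d);
    Mu = X * B.t();
    if (nf > 0) {
      List up = cpp_update_R(Z, Mu, phi, r, delta_sq, proposal_scale);
      r = as<vec>(up["r"]);
      fill_corr(r, p, R);
    }
    draws(s, arma::span(0, p * d - 1)) = b.t();
    if (nf > 0) draws(s, arma::span(p * d, p * d + nf - 1)) = r.t();
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws);
}

// ---------------------------------------------------------------------------
// Genz separation-of-variables randomized-QMC orthant probabilities for the
// location-shifted multivariate t: P(sign pattern of T) with
// T ~ St_p(mu, Sigma, nu).  Conditioning on chi2_nu reduces each point to a
// sequentially-conditioned normal rectangle probability; a Richtmyer lattice
// with random shifts gives the error estimate.

// small counter-based generator (splitmix64) for the random shifts only
static double sm64(uint64_t& s) {
  s += 0x9E3779B97f4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z = z ^ (z >> 31);
  return (z >> 11) * (1.0 / 9007199254740992.0);
}

// depth-first walk of the sign-pattern tree for one (subject, lattice
// point): coordinates are conditioned sequentially and the two sign
// branches share every quantity computed before they split, so evaluating
// all 2^p orthants costs ~(2^p - 1) pnorm calls instead of p * 2^p.
// leaf index: coordinate 0 is the most significant bit.
static void orthant_tree(const mat& C, const double* b0, const double* w,
                         int p, int j, int prefix, double f,
                         const double* y, double* leaf) {
  double num = 0.0;
  for (int k = 0; k < j; ++k) num += C(j, k) * y[k];
  double Phi = R::pnorm((b0[j] - num) / C(j, j), 0.0, 1.0, 1, 0);
  for (int bit = 0; bit <= 1; ++bit) {
    double dlo = bit ? Phi : 0.0;
    double dhi = bit ? 1.0 : Phi;
    double fnew = f * (dhi - dlo);
    int pre = (prefix << 1) | bit;
    if (j == p - 1) {
      leaf[pre] += fnew;
    } else if (fnew > 0.0) {
      double uu = dlo + w[j + 1] * (dhi - dlo);
      uu = std::min(std::max(uu, 1e-16), 1.0 - 1e-16);
      double ynew[8];
      for (int k = 0; k < j; ++k) ynew[k] = y[k];
      ynew[j] = R::qnorm(uu, 0.0, 1.0, 1, 0);
      orthant_tree(C, b0, w, p, j + 1, pre, fnew, ynew, leaf);
    }
  }
}

// patterns: K x p matrix of 0/1; returns list(prob = n x K, error = n x K)
// [[Rcpp::export]]
Rcpp::List cpp_mvt_orthant_batch(const arma::mat& Mu, const arma::mat& sigma,
                                 double nu, const arma::imat& patterns,
                                 double abseps, int max_points, int seed) {
  int n = Mu.n_rows, p = Mu.n_cols, K = patterns.n_rows;
  const int n_shift = 10;
  int n_leaf = 1 << p;
  mat C = arma::chol(sigma, "lower");

  // map each requested pattern to its leaf index
  arma::ivec leaf_of(K);
  for (int kk = 0; kk < K; ++kk) {
    int idx = 0;
    for (int j = 0; j < p; ++j) idx = (idx << 1) | patterns(kk, j);
    leaf_of(kk) = idx;
  }

  static const double primes[12] = {2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37};
  vec q(p);
  for (int j = 0; j < p; ++j) q(j) = std::sqrt(primes[j]);

  // random shifts, deterministic in `seed`
  mat shift(n_shift, p);
  uint64_t st = (uint64_t)seed * 0x9E3779B97f4A7C15ULL + 12345ULL;
  for (int s = 0; s < n_shift; ++s)
    for (int j = 0; j < p; ++j) shift(s, j) = sm64(st);

  arma::cube sum(n, n_leaf, n_shift, arma::fill::zeros);
  arma::mat prob(n, K), err(n, K);
  int done_points = 0;
  int batch = 128;
  std::vector<double> w(p), b0(p);
  double leaf[256];
  for (;;) {
    for (int s = 0; s < n_shift; ++s) {
      for (int t = done_points; t < done_points + batch; ++t) {
        // periodized Richtmyer lattice point
        for (int j = 0; j < p; ++j) {
          double u = (t + 1) * q(j) + shift(s, j);
          u -= std::floor(u);
          w[j] = std::fabs(2.0 * u - 1.0);
        }
        // chi scale shared across subjects and patterns: conditioning the t
        // vector on chi2_nu leaves a normal rectangle with scaled bounds
        double chi2 = R::qchisq(std::min(w[0], 1.0 - 1e-16), nu, 1, 0);
        double sc = std::sqrt(chi2 / nu);
        for (int i = 0; i < n; ++i) {
          // standardized upper bounds sc * (0 - mu) for the normal vector
          for (int j = 0; j < p; ++j) b0[j] = sc * (0.0 - Mu(i, j));
          for (int l = 0; l < n_leaf; ++l) leaf[l] = 0.0;
          double ybuf[8];
          orthant_tree(C, b0.data(), w.data(), p, 0, 0, 1.0, ybuf, leaf);
          for (int l = 0; l < n_leaf; ++l) sum(i, l, s) += leaf[l];
        }
      }
    }
    done_points += batch;
    // error estimate from the spread of the shifted-lattice means,
    // over the requested patterns only
    double maxerr = 0.0;
    for (int i = 0; i < n; ++i)
      for (int kk = 0; kk < K; ++kk) {
        int l = leaf_of(kk);
        double mbar = 0.0, v = 0.0;
        for (int s = 0; s < n_shift; ++s) mbar += sum(i, l, s);
        mbar /= (double)n_shift * done_points;
        for (int s = 0; s < n_shift; ++s) {
          double dif = sum(i, l, s) / done_points - mbar;
          v += dif * dif;
        }
        double se = 3.0 * std::sqrt(v / (n_shift * (n_shift - 1.0)));
        prob(i, kk) = std::min(std::max(mbar, 0.0), 1.0);
        err(i, kk) = se;
        if (se > maxerr) maxerr = se;
      }
    if (maxerr < abseps || done_points >= max_points) break;
    batch = std::min(done_points, max_points - done_points);
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["prob"] = prob, _["error"] = err,
                      _["points"] = done_points);
}
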