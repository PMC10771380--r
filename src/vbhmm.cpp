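// Variational-Bayes inference for a Gaussian-emission HMM with
// Dirichlet priors on the initial/transition probabilities and
// Normal-Wishart priors on the per-state emission parameters.
// The free energy (negative ELBO) is computed every iteration and is
// monotonically non-increasing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double ln_mv_gamma(int p, double a) {
  double r = 0.25 * p * (p - 1) * std::log(M_PI);
  for (int j = 1; j <= p; ++j) r += R::lgammafn(a + 0.5 * (1 - j));
  return r;
}

// KL(Dirichlet(a) || Dirichlet(b)), elementwise vectors
static double kl_dirichlet(const vec &a, const vec &b) {
  double a0 = accu(a), b0 = accu(b);
  double kl = R::lgammafn(a0) - R::lgammafn(b0);
  for (uword i = 0; i < a.n_elem; ++i) {
    kl += R::lgammafn(b(i)) - R::lgammafn(a(i));
    kl += (a(i) - b(i)) * (R::digamma(a(i)) - R::digamma(a0));
  }
  return kl;
}

struct FBResult {
  mat gamma;     // K x T
  mat xi_sum;    // K x K
  double lnZ;
};

// Scaled forward-backward on sub-normalized parameters given as logs.
static FBResult forward_backward(const vec &log_pi, const mat &log_A,
                                 const mat &log_B) {
  const uword K = log_B.n_rows, T = log_B.n_cols;
  mat Astar = exp(log_A);
  vec pistar = exp(log_pi);
  rowvec offset = max(log_B, 0);
  mat Bstar = exp(log_B.each_row() - offset);
  mat alpha(K, T), beta(K, T);
  vec c(T);
  alpha.col(0) = pistar % Bstar.col(0);
  c(0) = accu(alpha.col(0));
  alpha.col(0) /= c(0);
  for (uword t = 1; t < T; ++t) {
    alpha.col(t) = (Astar.t() * alpha.col(t - 1)) % Bstar.col(t);
    c(t) = accu(alpha.col(t));
    alpha.col(t) /= c(t);
  }
  beta.col(T - 1).ones();
  mat xi_sum(K, K, fill::zeros);
  for (uword t = T - 1; t >= 1; --t) {
    vec bb = Bstar.col(t) % beta.col(t);
    xi_sum += (alpha.col(t - 1) * bb.t()) % Astar / c(t);
    beta.col(t - 1) = (Astar * bb) / c(t);
  }
  FBResult r;
  r.gamma = alpha % beta;
  r.gamma.each_row() /= sum(r.gamma, 0);  // guard rounding
  r.xi_sum = xi_sum;
  r.lnZ = accu(log(c)) + accu(offset);
  return r;
}

// [[Rcpp::export]]
Rcpp::List forward_backward_cpp(const arma::vec &log_pi, const arma::mat &log_A,
                                const arma::mat &log_B) {
  FBResult r = forward_backward(log_pi, log_A, log_B);
  return Rcpp::List::create(Rcpp::Named("gamma") = r.gamma,
                            Rcpp::Named("xi_sum") = r.xi_sum,
                            Rcpp::Named("loglik") = r.lnZ);
}

// Log-domain Viterbi; ties broken toward the lower state index.
// [[Rcpp::export]]
arma::ivec viterbi_cpp(const arma::vec &log_pi, const arma::mat &log_A,
                       const arma::mat &log_B) {
  const uword K = log_B.n_rows, T = log_B.n_cols;
  mat delta(K, T);
  umat psi(K, T);
  delta.col(0) = log_pi + log_B.col(0);
  for (uword t = 1; t < T; ++t) {
    for (uword j = 0; j < K; ++j) {
      double best = -datum::inf;
      uword arg = 0;
      for (uword i = 0; i < K; ++i) {
        double v = delta(i, t - 1) + log_A(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(j, t) = best + log_B(j, t);
      psi(j, t) = arg;
    }
  }
  ivec path(T);
  uword last = 0;
  double best = -datum::inf;
  for (uword i = 0; i < K; ++i)
    if (delta(i, T - 1) > best) { best = delta(i, T - 1); last = i; }
  path(T - 1) = last + 1;
  for (uword t = T - 1; t >= 1; --t) {
    last = psi(last, t);
    path(t - 1) = last + 1;
  }
  return path;
}

// Full VB iteration loop.  X is N x T, gamma_init K x T.
// [[Rcpp::export]]
Rcpp::List vb_hmm_cpp(const arma::mat &X, const arma::mat &gamma_init,
                      double alpha0_pi, double alpha0_A,
                      double beta0, double nu0,
                      const arma::mat &W0inv, const arma::vec &m0,
                      double tol, int max_iter) {
  const uword N = X.n_rows, T = X.n_cols, K = gamma_init.n_rows;
  const double ln2pi = std::log(2.0 * M_PI);

  double sign, logdet_W0inv;
  log_det(logdet_W0inv, sign, W0inv);
  const double logdet_W0 = -logdet_W0inv;

  mat gamma = gamma_init;
  // initial transition stats from products of consecutive responsibilities
  mat xi_sum(K, K, fill::zeros);
  for (uword t = 0; t + 1 < T; ++t)
    xi_sum += gamma.col(t) * gamma.col(t + 1).t();

  vec alpha_pi(K), beta_q(K), nu_q(K);
  mat alpha_A(K, K), m_q(N, K);
  cube Winv(N, N, K), W(N, N, K);
  vec logdet_Wq(K);

  std::vector<double> fe_trace;
  double fe_prev = datum::inf;
  bool converged = false;
  int iter = 0;

  mat log_B(K, T);
  vec log_pi_star(K);
  mat log_A_star(K, K);

  for (iter = 1; iter <= max_iter; ++iter) {
    // ---- M-step (variational updates from current gamma / xi_sum) ----
    vec Nk = sum(gamma, 1);
    alpha_pi = alpha0_pi + gamma.col(0);
    alpha_A = alpha0_A + xi_sum;
    for (uword k = 0; k < K; ++k) {
      double nk = Nk(k);
      vec xbar = (nk > 1e-12) ? vec(X * gamma.row(k).t() / nk)
                              : vec(N, fill::zeros);
      mat Xc = X.each_col() - xbar;
      mat Xw = Xc.each_row() % sqrt(gamma.row(k));
      mat scatter = Xw * Xw.t();                   // Nk * S_k
      beta_q(k) = beta0 + nk;
      nu_q(k) = nu0 + nk;
      m_q.col(k) = (beta0 * m0 + nk * xbar) / beta_q(k);
      vec d = xbar - m0;
      Winv.slice(k) = W0inv + scatter + (beta0 * nk / (beta0 + nk)) * (d * d.t());
      Winv.slice(k) = symmatu(0.5 * (Winv.slice(k) + Winv.slice(k).t()));
      W.slice(k) = inv_sympd(Winv.slice(k));
      double ld;
      log_det(ld, sign, Winv.slice(k));
      logdet_Wq(k) = -ld;
    }

    // ---- E-step ----
    double dig_sum_pi = R::digamma(accu(alpha_pi));
    for (uword k = 0; k < K; ++k)
      log_pi_star(k) = R::digamma(alpha_pi(k)) - dig_sum_pi;
    for (uword i = 0; i < K; ++i) {
      double dig_row = R::digamma(accu(alpha_A.row(i)));
      for (uword j = 0; j < K; ++j)
        log_A_star(i, j) = R::digamma(alpha_A(i, j)) - dig_row;
    }
    for (uword k = 0; k < K; ++k) {
      double elogdet = logdet_Wq(k) + N * std::log(2.0);
      for (uword j = 1; j <= N; ++j)
        elogdet += R::digamma(0.5 * (nu_q(k) + 1 - j));
      mat L = chol(W.slice(k), "lower");
      mat Z = L.t() * (X.each_col() - m_q.col(k));
      rowvec quad = nu_q(k) * sum(square(Z), 0);
      log_B.row(k) = -0.5 * (quad + N / beta_q(k)) +
        0.5 * (elogdet - N * ln2pi);
    }
    FBResult fb = forward_backward(log_pi_star, log_A_star, log_B);
    gamma = fb.gamma;
    xi_sum = fb.xi_sum;

    // ---- free energy ----
    double kl = kl_dirichlet(alpha_pi, vec(K, fill::value(alpha0_pi)));
    for (uword i = 0; i < K; ++i)
      kl += kl_dirichlet(alpha_A.row(i).t(), vec(K, fill::value(alpha0_A)));
    for (uword k = 0; k < K; ++k) {
      double elogdet = logdet_Wq(k) + N * std::log(2.0);
      for (uword j = 1; j <= N; ++j)
        elogdet += R::digamma(0.5 * (nu_q(k) + 1 - j));
      // Gaussian part, expected over the Wishart
      vec dm = m_q.col(k) - m0;
      double kl_gauss = 0.5 * (N * (beta0 / beta_q(k) - 1.0 -
                                    std::log(beta0 / beta_q(k))) +
                               beta0 * nu_q(k) *
                                 as_scalar(dm.t() * W.slice(k) * dm));
      // Wishart part
      double kl_wish = 0.5 * (nu_q(k) - nu0) * elogdet -
        0.5 * nu_q(k) * N +
        0.5 * nu_q(k) * trace(W0inv * W.slice(k)) -
        0.5 * nu_q(k) * N * std::log(2.0) - 0.5 * nu_q(k) * logdet_Wq(k) -
        ln_mv_gamma(N, 0.5 * nu_q(k)) +
        0.5 * nu0 * N * std::log(2.0) + 0.5 * nu0 * logdet_W0 +
        ln_mv_gamma(N, 0.5 * nu0);
      kl += kl_gauss + kl_wish;
    }
    double fe = -(fb.lnZ - kl);
    fe_trace.push_back(fe);
    if (std::abs(fe_prev - fe) < tol * std::abs(fe)) { converged = true; break; }
    fe_prev = fe;
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
    Rcpp::Named("alpha_pi") = alpha_pi,
    Rcpp::Named("alpha_A") = alpha_A,
    Rcpp::Named("beta") = beta_q,
    Rcpp::Named("nu") = nu_q,
    Rcpp::Named("m") = m_q,
    Rcpp::Named("Winv") = Winv,
    Rcpp::Named("gamma") = gamma,
    Rcpp::Named("xi_sum") = xi_sum,
    Rcpp::Named("free_energy_trace") = fe_trace,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}
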