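// Scaled forward filtering for a hidden Markov chain with precomputed
// per-frame emission log-likelihoods. The first frame carries no emission
// term (the AR likelihood conditions on x_1), which callers encode by
// passing logB(0, s) == 0 for all s.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat forward_filter(const arma::mat& logB, const arma::mat& Pi,
                                const arma::vec& init, double& loglik) {
  const int T = logB.n_rows, S = logB.n_cols;
  arma::mat alpha(T, S);
  loglik = 0.0;
  arma::rowvec prev(S);
  for (int t = 0; t < T; ++t) {
    arma::rowvec b = logB.row(t);
    double m = b.max();
    arma::rowvec emis = arma::exp(b - m);
    arma::rowvec pred(S);
    if (t == 0) {
      pred = init.t();
    } else {
      pred = prev * Pi;
    }
    arma::rowvec a = pred % emis;
    double c = arma::accu(a);
    if (!(c > 0)) { // total underflow guard: fall back to prediction
      a = pred;
      c = arma::accu(a);
      m = 0.0;
    }
    alpha.row(t) = a / c;
    prev = alpha.row(t);
    loglik += std::log(c) + m;
  }
  return alpha;
}

// Draw z_{1:T} ~ P(z | x, theta) by forward filtering / backward sampling.
// u: T iid Uniform(0,1) draws supplied by the caller (keeps all randomness
// under R's RNG). Returns 1-based state labels.
// [[Rcpp::export]]
IntegerVector ffbs_sample_cpp(const arma::mat& logB, const arma::mat& Pi,
                              const arma::vec& init, const arma::vec& u) {
  const int T = logB.n_rows, S = logB.n_cols;
  double ll;
  arma::mat alpha = forward_filter(logB, Pi, init, ll);
  IntegerVector z(T);
  // sample z_T
  {
    arma::rowvec p = alpha.row(T - 1);
    double cum = 0.0; int pick = S - 1;
    for (int s = 0; s < S; ++s) { cum += p(s); if (u(T - 1) <= cum) { pick = s; break; } }
    z[T - 1] = pick + 1;
  }
  for (int t = T - 2; t >= 0; --t) {
    int znext = z[t + 1] - 1;
    arma::rowvec p = alpha.row(t) % Pi.col(znext).t();
    double c = arma::accu(p);
    if (!(c > 0)) p = alpha.row(t); else p /= c;
    double cum = 0.0; int pick = S - 1;
    for (int s = 0; s < S; ++s) { cum += p(s); if (u(t) <= cum) { pick = s; break; } }
    z[t] = pick + 1;
  }
  return z;
}

// Marginal log-likelihood log P(x | theta) by the forward algorithm.
// [[Rcpp::export]]
double forward_loglik_cpp(const arma::mat& logB, const arma::mat& Pi,
                          const arma::vec& init) {
  double ll;
  forward_filter(logB, Pi, init, ll);
  return ll;
}

// Time-wise posterior state marginals by forward-backward (used for
// fixed-parameter checks; Gibbs marginals come from draw frequencies).
// [[Rcpp::export]]
arma::mat forward_backward_cpp(const arma::mat& logB, const arma::mat& Pi,
                               const arma::vec& init) {
  const int T = logB.n_rows, S = logB.n_cols;
  double ll;
  arma::mat alpha = forward_filter(logB, Pi, init, ll);
  arma::mat gamma(T, S);
  arma::rowvec beta(S, arma::fill::ones);
  gamma.row(T - 1) = alpha.row(T - 1);
  for (int t = T - 2; t >= 0; --t) {
    arma::rowvec b = logB.row(t + 1);
    double m = b.max();
    arma::rowvec emis = arma::exp(b - m);
    beta = (Pi * (emis % beta).t()).t();
    beta /= arma::accu(beta); // rescale; gamma is renormalized anyway
    arma::rowvec g = alpha.row(t) % beta;
    gamma.row(t) = g / arma::accu(g);
  }
  return gamma;
}
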