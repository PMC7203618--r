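// Hamiltonian Monte Carlo for Bayesian logistic regression with independent
// normal priors. The mass matrix is the negative log-posterior Hessian at
// the MAP (passed in as its upper Cholesky factor), which preconditions the
// near-Gaussian posterior so short trajectories mix well. Step size is
// adapted during warmup toward a target acceptance rate, then frozen.

#include <RcppArmadillo.h>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct XorShift {
  uint64_t s0, s1;
  explicit XorShift(uint64_t seed) {
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    auto mix = [](uint64_t z) {
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = mix(z);
    z += 0x9e3779b97f4a7c15ULL;
    s1 = mix(z);
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() {
    double u = (next() >> 11) * (1.0 / 9007199254740992.0);
    return u > 0 ? u : 5e-324;
  }
  double normal() {
    // Box-Muller (one value per call; simple and deterministic)
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  int below(int n) { return static_cast<int>(unif() * n) % n; }
};

inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

// negative log posterior (up to a constant)
double nlp(const vec& beta, const mat& X, const vec& y, const vec& prec) {
  vec eta = X * beta;
  double ll = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i)
    ll += softplus(eta[i]) - y[i] * eta[i];
  return ll + 0.5 * dot(prec, square(beta));
}

vec nlp_grad(const vec& beta, const mat& X, const vec& y, const vec& prec) {
  vec eta = X * beta;
  vec p = 1.0 / (1.0 + exp(-eta));
  return X.t() * (p - y) + prec % beta;
}

} // namespace

// [[Rcpp::export(name = ".hmc_logistic_cpp")]]
Rcpp::List hmc_logistic_cpp(const arma::mat& X, const arma::vec& y,
                            const arma::vec& prior_prec,
                            const arma::vec& beta_init,
                            const arma::mat& cholU, // upper: H = U' U
                            int warmup, int iter, int L_max,
                            double eps0, double accept_target, int seed) {
  const uword p = X.n_cols;
  XorShift rng(static_cast<uint64_t>(seed));

  vec beta = beta_init;
  double cur_nlp = nlp(beta, X, y, prior_prec);
  vec cur_grad = nlp_grad(beta, X, y, prior_prec);

  mat samples(iter, p);
  double eps = eps0;
  double log_eps = std::log(eps0);
  int accepted = 0;

  auto minv = [&](const vec& r) {
    // H^{-1} r via two triangular solves
    vec t = solve(trimatl(cholU.t()), r);
    return vec(solve(trimatu(cholU), t));
  };

  const int total = warmup + iter;
  for (int it = 0; it < total; ++it) {
    // momentum r ~ N(0, H): r = U' z
    vec z(p);
    for (uword j = 0; j < p; ++j) z[j] = rng.normal();
    vec r = cholU.t() * z;

    vec b = beta;
    vec g = cur_grad;
    vec r0 = r;
    int L = 1 + rng.below(L_max);
    for (int l = 0; l < L; ++l) {
      r -= 0.5 * eps * g;
      b += eps * minv(r);
      g = nlp_grad(b, X, y, prior_prec);
      r -= 0.5 * eps * g;
    }
    double prop_nlp = nlp(b, X, y, prior_prec);
    double h0 = cur_nlp + 0.5 * dot(r0, minv(r0));
    double h1 = prop_nlp + 0.5 * dot(r, minv(r));
    double log_accept = h0 - h1;
    bool ok = std::isfinite(log_accept) &&
      std::log(rng.unif()) < log_accept;
    if (ok) {
      beta = b;
      cur_nlp = prop_nlp;
      cur_grad = g;
    }
    if (it < warmup) {
      double a = ok ? 1.0 : std::min(1.0, std::exp(log_accept));
      if (!std::isfinite(a)) a = 0.0;
      // Robbins-Monro step-size adaptation
      double gain = 0.3 / std::sqrt(1.0 + it);
      log_eps += gain * (a - accept_target);
      log_eps = std::min(std::max(log_eps, std::log(1e-4)), std::log(2.0));
      eps = std::exp(log_eps);
    } else {
      if (ok) ++accepted;
      samples.row(it - warmup) = beta.t();
    }
  }

  return Rcpp::List::create(
    Rcpp::_["samples"] = samples,
    Rcpp::_["accept_rate"] = iter > 0 ? double(accepted) / iter : NA_REAL,
    Rcpp::_["eps"] = eps);
}
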