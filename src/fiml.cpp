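// FIML engine for the twin-family PGS transmission model.
//
// The per-family Gaussian likelihood is evaluated on grouped missingness
// patterns via sufficient statistics (n, mean, ML scatter per pattern), so
// one objective evaluation costs O(#patterns * 6^3) regardless of sample
// size. The model-implied moments are the closed-form expressions; the R
// level carries an independent path-algebra construction tested against
// these formulas.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Unconstrained parameter vector theta (length 10):
// log V_PGS, atanh r_a, log V_ADHD, atanh r_MZ, atanh r_DZ,
// g_tw, g_m, g_f, mu_PGS, mu_ADHD.
// Variable order: pgs_m, pgs_f, pgs_t1, pgs_t2, pheno_t1, pheno_t2.

static void implied_moments_theta(const vec &th, int zyg, vec &mu, mat &S) {
  const double V  = std::exp(th[0]);
  const double ra = std::tanh(th[1]);
  const double VA = std::exp(th[2]);
  const double rz = (zyg == 0) ? std::tanh(th[3]) : std::tanh(th[4]);
  const double gt = th[5], gm = th[6], gf = th[7];
  const double muP = th[8], muA = th[9];

  const double c   = 0.5 * V * (1.0 + ra);        // parent-child PGS cov
  const double ctt = (zyg == 0) ? V : c;          // twin-twin PGS cov

  mu.set_size(6);
  mu[0] = muP; mu[1] = muP; mu[2] = muP; mu[3] = muP;
  mu[4] = muA; mu[5] = muA;

  const double covMA = gt * c + gm * V + gf * ra * V;
  const double covFA = gt * c + gf * V + gm * ra * V;
  const double covTown = gt * V + (gm + gf) * c;
  const double covTco  = gt * ctt + (gm + gf) * c;
  const double vphen = (gt * gt + gm * gm + gf * gf) * V +
    2.0 * gt * (gm + gf) * c + 2.0 * gm * gf * ra * V + VA;
  const double covAA = gt * gt * ctt + 2.0 * gt * (gm + gf) * c +
    (gm * gm + gf * gf) * V + 2.0 * gm * gf * ra * V + rz * VA;

  S.set_size(6, 6);
  S(0, 0) = V;  S(1, 1) = V;  S(2, 2) = V;  S(3, 3) = V;
  S(0, 1) = ra * V;
  S(0, 2) = c;  S(0, 3) = c;  S(1, 2) = c;  S(1, 3) = c;
  S(2, 3) = ctt;
  S(0, 4) = covMA;  S(0, 5) = covMA;
  S(1, 4) = covFA;  S(1, 5) = covFA;
  S(2, 4) = covTown; S(3, 5) = covTown;
  S(2, 5) = covTco;  S(3, 4) = covTco;
  S(4, 4) = vphen;  S(5, 5) = vphen;  S(4, 5) = covAA;
  S = symmatu(S);
}

struct Pattern {
  int zyg;      // 0 = MZ, 1 = DZ
  uvec idx;     // 0-based observed-variable indices
  double n;
  vec mean;
  mat scatter;  // ML (divisor n) within-pattern covariance
};

static std::vector<Pattern> unpack_patterns(const Rcpp::List &patterns) {
  std::vector<Pattern> out;
  out.reserve(patterns.size());
  for (int i = 0; i < patterns.size(); ++i) {
    Rcpp::List p = patterns[i];
    Pattern q;
    q.zyg = Rcpp::as<int>(p["zyg"]);
    Rcpp::IntegerVector idx1 = p["idx"];
    q.idx.set_size(idx1.size());
    for (int j = 0; j < idx1.size(); ++j) q.idx[j] = idx1[j] - 1;
    q.n = Rcpp::as<double>(p["n"]);
    q.mean = Rcpp::as<vec>(p["mean"]);
    q.scatter = Rcpp::as<mat>(p["scatter"]);
    out.push_back(q);
  }
  return out;
}

static const double BIG = 1e12;

// -2.log L is not used; this returns the negative log-likelihood.
static double negll_moments(const vec &mu, const mat &S,
                            const std::vector<Pattern> &pats, int zyg_filter) {
  const double l2pi = std::log(2.0 * M_PI);
  double nll = 0.0;
  for (const Pattern &p : pats) {
    if (zyg_filter >= 0 && p.zyg != zyg_filter) continue;
    const unsigned int k = p.idx.n_elem;
    if (k == 0) continue;
    mat Sp = S.submat(p.idx, p.idx);
    mat Spi;
    if (!inv_sympd(Spi, Sp)) return BIG;
    double ldet, sign;
    log_det(ldet, sign, Sp);
    if (sign <= 0.0) return BIG;
    vec d = p.mean - mu.elem(p.idx);
    double tr = accu(Spi % p.scatter);
    double quad = as_scalar(d.t() * Spi * d);
    nll += 0.5 * p.n * (k * l2pi + ldet + tr + quad);
  }
  if (!std::isfinite(nll)) return BIG;
  return nll;
}

static double negll_theta(const vec &th, const std::vector<Pattern> &pats) {
  vec mu0, mu1;
  mat S0, S1;
  implied_moments_theta(th, 0, mu0, S0);
  implied_moments_theta(th, 1, mu1, S1);
  double nll = negll_moments(mu0, S0, pats, 0);
  if (nll >= BIG) return BIG;
  double nll1 = negll_moments(mu1, S1, pats, 1);
  if (nll1 >= BIG) return BIG;
  return nll + nll1;
}

static vec expand_theta(const vec &theta_free, const uvec &free_idx,
                        const vec &theta_full) {
  vec th = theta_full;
  for (unsigned int i = 0; i < free_idx.n_elem; ++i)
    th[free_idx[i] - 1] = theta_free[i];
  return th;
}

// [[Rcpp::export]]
double cpp_fiml_negll(const arma::vec &theta_free,
                      const arma::uvec &free_idx,
                      const arma::vec &theta_full,
                      Rcpp::List patterns) {
  std::vector<Pattern> pats = unpack_patterns(patterns);
  return negll_theta(expand_theta(theta_free, free_idx, theta_full), pats);
}

// Central-difference gradient of the negative log-likelihood in the free
// parameters; the pattern list is unpacked once per call.
// [[Rcpp::export]]
arma::vec cpp_fiml_grad(const arma::vec &theta_free,
                        const arma::uvec &free_idx,
                        const arma::vec &theta_full,
                        Rcpp::List patterns) {
  std::vector<Pattern> pats = unpack_patterns(patterns);
  const unsigned int m = theta_free.n_elem;
  vec g(m);
  for (unsigned int i = 0; i < m; ++i) {
    double h = 1e-6 * std::max(1.0, std::fabs(theta_free[i]));
    vec tp = theta_free, tm = theta_free;
    tp[i] += h;
    tm[i] -= h;
    double fp = negll_theta(expand_theta(tp, free_idx, theta_full), pats);
    double fm = negll_theta(expand_theta(tm, free_idx, theta_full), pats);
    g[i] = (fp - fm) / (2.0 * h);
  }
  return g;
}

// Negative log-likelihood of an unstructured Gaussian (mu, Sigma) over one
// group's patterns (idx here indexes into mu/Sigma). Used by the saturated
// model fit.
// [[Rcpp::export]]
double cpp_mvn_negll(const arma::vec &mu, const arma::mat &Sigma,
                     Rcpp::List patterns) {
  std::vector<Pattern> pats = unpack_patterns(patterns);
  return negll_moments(mu, Sigma, pats, -1);
}

// [[Rcpp::export]]
Rcpp::List cpp_implied_moments(const arma::vec &theta, int zyg) {
  vec mu;
  mat S;
  implied_moments_theta(theta, zyg, mu, S);
  return Rcpp::List::create(Rcpp::Named("mean") = mu, Rcpp::Named("cov") = S);
}
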