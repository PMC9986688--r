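#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Retrospective log-likelihood of the observed standardized PRS values
// given phenotype (status, age), under the age-dependent polygenic
// hazard model.  Per individual i:
//   log [ P(pheno_i | x_K = z_i) * phi(z_i) / Int P(pheno_i | u) phi(u) du ]
// with P(pheno | x_K) integrating the residual polygenotype x_R out by
// Gauss-Hermite quadrature, and the denominator integrating over u by
// the same rule.  `nodes` are sqrt(2)-scaled Gauss-Hermite abscissae and
// `wts` the matching weights normalised to sum to 1, so that
// E[f(Z)] ~ sum(wts * f(nodes)) for Z ~ N(0,1).
//
// lambda0, sigma: baseline hazard and polygenic SD per yearly age,
//   ages age_min .. age_min + A - 1.
// status: 1 case / 0 control; age: phenotype age; z: standardized PRS.
// [[Rcpp::export]]
double rl_loglik_cpp(NumericVector lambda0, NumericVector sigma,
                     int age_min, IntegerVector status, IntegerVector age,
                     NumericVector z, double alpha,
                     NumericVector nodes, NumericVector wts) {
  const int A = lambda0.size();
  const int Q = nodes.size();
  const int n = status.size();
  if (sigma.size() != A) stop("lambda0/sigma length mismatch");
  if (age.size() != n || z.size() != n) stop("cohort vector length mismatch");
  if (alpha < 0.0 || alpha >= 1.0) stop("alpha must lie in [0, 1)");
  const double b = std::sqrt(1.0 - alpha * alpha);
  const double LOG_SQRT_2PI = 0.9189385332046727417803297364056;

  // Denominators: P(status, t) marginal over x_K ~ N(0,1), via the
  // double quadrature over (u, x_R); c = alpha*u + b*x_R on Q*Q nodes.
  std::vector<double> cum(Q * Q, 0.0);
  std::vector<double> denom_ctrl(A), denom_case(A);
  for (int a = 0; a < A; ++a) {
    double dc = 0.0, dd = 0.0;
    for (int k = 0; k < Q; ++k) {
      for (int j = 0; j < Q; ++j) {
        const int m = k * Q + j;
        const double c = alpha * nodes[k] + b * nodes[j];
        const double w = wts[k] * wts[j];
        const double surv = std::exp(-cum[m]);
        const double haz = lambda0[a] * std::exp(sigma[a] * c);
        dc += w * surv;
        dd += w * surv * haz;
        cum[m] += haz;
      }
    }
    denom_ctrl[a] = dc;
    denom_case[a] = dd;
  }

  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    const int ai = age[i] - age_min;
    if (ai < 0 || ai >= A) stop("cohort age outside baseline range");
    double num = 0.0;
    for (int j = 0; j < Q; ++j) {
      const double c = alpha * z[i] + b * nodes[j];
      double lam = 0.0;
      for (int u = 0; u < ai; ++u)
        lam += lambda0[u] * std::exp(sigma[u] * c);
      double p = std::exp(-lam);
      if (status[i] == 1)
        p *= lambda0[ai] * std::exp(sigma[ai] * c);
      num += wts[j] * p;
    }
    const double den = status[i] == 1 ? denom_case[ai] : denom_ctrl[ai];
    const double contrib = std::log(num) - std::log(den)
      - 0.5 * z[i] * z[i] - LOG_SQRT_2PI;
    if (!std::isfinite(contrib))
      stop("non-finite likelihood contribution at record %d (age %d, z %g)",
           i + 1, age[i], z[i]);
    ll += contrib;
  }
  return ll;
}

// Discrete-time cohort draw: for each individual with effective
// polygenotype c_i = alpha*x_K + sqrt(1-alpha^2)*x_R, an event occurs at
// age t with probability 1 - exp(-lambda(t|c)), years age_min ..
// censor_i - 1.  `unif` is a pre-drawn n x A uniform matrix (column u =
// age index u) so that all randomness stays in R's generator.  Returns
// the onset age, or NA when no event occurs before the censor age.
// [[Rcpp::export]]
IntegerVector sim_onset_cpp(NumericVector lambda0, NumericVector sigma,
                            int age_min, NumericVector ceff,
                            IntegerVector censor, NumericMatrix unif) {
  const int A = lambda0.size();
  const int n = ceff.size();
  IntegerVector onset(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    const int last = censor[i] - age_min;   // simulate ages < censor
    for (int u = 0; u < last && u < A; ++u) {
      const double lam = lambda0[u] * std::exp(sigma[u] * ceff[i]);
      if (unif(i, u) < -std::expm1(-lam)) {
        onset[i] = age_min + u;
        break;
      }
    }
  }
  return onset;
}
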