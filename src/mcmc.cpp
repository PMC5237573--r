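#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs sampler for the mixture-prior multi-marker models.
//
// Model: y = 1 mu + X a + W d + e,  e ~ N(0, ve I), ve fixed.
// Prior per SNP j: indicator gamma_j ~ Bern(pld); the joint effect is drawn
// from a base distribution F when gamma_j = 1 and from eps * F otherwise
// (the whole effect vector is scaled, so the small-component additive scale
// is eps * s_a). The additive marginal of F is a t with df_t degrees of
// freedom and scale s_a, represented as a normal scale mixture with a
// per-SNP latent variance multiplier v_j ~ InvGamma(df/2, df/2). Conditional
// on the additive effect, the dominance effect is
//   d_j | a_j ~ N(mu_h * |a_j|, sigma_h^2 * a_j^2),
// identical under both mixture components (the conditional is invariant to
// the joint eps-scaling).
//
// Updates per cycle: mu (normal full conditional); for each SNP in fixed
// ascending order: v_j (inverse-gamma full conditional), then
//   BayesC: (gamma_j, a_j) exactly from their joint full conditional with a
//           integrated per component;
//   BayesD: the BayesC joint draw serves as an independence
//           Metropolis-Hastings proposal, accepted with the ratio of the
//           dominance-prior densities p(d_j | a') / p(d_j | a) (the only
//           factor the proposal omits), then d_j from its conjugate normal
//           full conditional.
// With likelihood_on = FALSE all data terms are dropped and the sampler
// draws from the prior (used by the prior-reproduction correctness checks).

static inline double log_norm_pdf(double x, double m, double v) {
  return -0.5 * std::log(2.0 * M_PI * v) - 0.5 * (x - m) * (x - m) / v;
}

// [[Rcpp::export]]
List mcmc_mixture_cpp(NumericVector y, NumericMatrix X, NumericMatrix W,
                      double ve, double pld, double eps, double df_t,
                      double s2a, double mu_h, double sigma_h, int n_cycles,
                      int burn_in, int thin, bool dominance,
                      bool likelihood_on = true) {
  int N = X.nrow(), M = X.ncol();
  int n_store = (n_cycles - burn_in) / thin;
  NumericVector mu_s(n_store);
  NumericMatrix a_s(n_store, M), d_s(dominance ? n_store : 0,
                                     dominance ? M : 0);
  IntegerMatrix g_s(n_store, M);

  std::vector<double> a(M, 0.0), d(M, 0.0), v(M, 1.0);
  std::vector<int> gamma(M, 0);
  std::vector<double> xx(M), ww(M);
  std::vector<bool> skip(M);
  double mu = 0.0;

  const double *Xp = X.begin(), *Wp = W.begin();
  for (int j = 0; j < M; j++) {
    const double *x = Xp + (size_t)N * j;
    double s = 0, s2 = 0;
    for (int i = 0; i < N; i++) { s += x[i]; s2 += x[i] * x[i]; }
    xx[j] = s2;
    skip[j] = (s2 - s * s / N) < 1e-12; // constant column: never updated
    if (dominance) {
      const double *w = Wp + (size_t)N * j;
      double t = 0;
      for (int i = 0; i < N; i++) t += w[i] * w[i];
      ww[j] = t;
    }
  }

  std::vector<double> e(N);
  if (likelihood_on) {
    mu = mean(y);
    for (int i = 0; i < N; i++) e[i] = y[i] - mu;
  }

  double log_prior_odds = std::log(pld) - std::log1p(-pld);
  double eps2 = eps * eps;
  double sh2 = sigma_h * sigma_h;
  int stored = 0;

  for (int cyc = 1; cyc <= n_cycles; cyc++) {
    if (cyc % 256 == 0) Rcpp::checkUserInterrupt();
    if (likelihood_on) { // mu: flat prior, normal full conditional
      double r = 0;
      for (int i = 0; i < N; i++) r += e[i];
      r += N * mu;
      double mu_new = R::rnorm(r / N, std::sqrt(ve / N));
      double dlt = mu_new - mu;
      for (int i = 0; i < N; i++) e[i] -= dlt;
      mu = mu_new;
    }

    for (int j = 0; j < M; j++) {
      if (skip[j] && likelihood_on) continue; // constant column
      const double *x = Xp + (size_t)N * j;

      // latent t-scale multiplier: v_j | a_j, gamma_j
      double s2_eff = gamma[j] ? s2a : eps2 * s2a;
      double rate = 0.5 * (df_t + a[j] * a[j] / s2_eff);
      v[j] = rate / R::rgamma(0.5 * (df_t + 1.0), 1.0);

      double t1 = s2a * v[j], t0 = eps2 * s2a * v[j];
      int g_new;
      double a_new;
      if (likelihood_on) {
        const int one = 1;
        double r = F77_CALL(ddot)(&N, x, &one, e.data(), &one) + xx[j] * a[j];
        double prec_dat = xx[j] / ve, rv = r / ve;
        double V1 = 1.0 / (prec_dat + 1.0 / t1), m1 = V1 * rv;
        double V0 = 1.0 / (prec_dat + 1.0 / t0), m0 = V0 * rv;
        double logL1 = 0.5 * std::log(V1 / t1) + 0.5 * m1 * m1 / V1;
        double logL0 = 0.5 * std::log(V0 / t0) + 0.5 * m0 * m0 / V0;
        double lo = log_prior_odds + logL1 - logL0;
        double p1 = 1.0 / (1.0 + std::exp(-lo));
        g_new = unif_rand() < p1 ? 1 : 0;
        a_new = g_new ? R::rnorm(m1, std::sqrt(V1)) : R::rnorm(m0, std::sqrt(V0));
      } else {
        g_new = unif_rand() < pld ? 1 : 0;
        a_new = R::rnorm(0.0, std::sqrt(g_new ? t1 : t0));
      }

      bool accept = true;
      if (dominance && sh2 > 0) {
        // independence-MH correction: the proposal omits p(d | a)
        double va_old = sh2 * a[j] * a[j], va_new = sh2 * a_new * a_new;
        if (a[j] == 0.0 && d[j] == 0.0) {
          accept = true; // initialization state, prior density degenerate
        } else if (va_new <= 0) {
          accept = false;
        } else {
          double la = log_norm_pdf(d[j], mu_h * std::fabs(a_new), va_new) -
                      log_norm_pdf(d[j], mu_h * std::fabs(a[j]), va_old);
          accept = std::log(unif_rand()) < la;
        }
      }
      if (accept) {
        if (likelihood_on) {
          const int one = 1;
          double ndlt = a[j] - a_new;
          if (ndlt != 0.0) F77_CALL(daxpy)(&N, &ndlt, x, &one, e.data(), &one);
        }
        a[j] = a_new;
        gamma[j] = g_new;
      }

      if (dominance) { // d_j | a_j: conjugate normal
        const double *w = Wp + (size_t)N * j;
        double pm = mu_h * std::fabs(a[j]), pv = sh2 * a[j] * a[j];
        double d_new;
        if (pv < 1e-300) {
          d_new = pm;
        } else if (likelihood_on) {
          const int one = 1;
          double rd = F77_CALL(ddot)(&N, w, &one, e.data(), &one) +
                      ww[j] * d[j];
          double V = 1.0 / (ww[j] / ve + 1.0 / pv);
          double m = V * (rd / ve + pm / pv);
          d_new = R::rnorm(m, std::sqrt(V));
        } else {
          d_new = R::rnorm(pm, std::sqrt(pv));
        }
        if (likelihood_on) {
          const int one = 1;
          double ndlt = d[j] - d_new;
          if (ndlt != 0.0) F77_CALL(daxpy)(&N, &ndlt, w, &one, e.data(), &one);
        }
        d[j] = d_new;
      }
    }

    if (cyc > burn_in && (cyc - burn_in) % thin == 0 && stored < n_store) {
      mu_s[stored] = mu;
      for (int j = 0; j < M; j++) {
        a_s(stored, j) = a[j];
        g_s(stored, j) = gamma[j];
        if (dominance) d_s(stored, j) = d[j];
      }
      stored++;
    }
  }

  List out = List::create(_["mu"] = mu_s, _["a"] = a_s, _["gamma"] = g_s);
  if (dominance) out["d"] = d_s;
  return out;
}
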