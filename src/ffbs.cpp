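#include <Rcpp.h>
using namespace Rcpp;

// Forward-filter backward-sample for the latent AR(1) daily level.
//
// State:       Z_t = mu + rho (Z_{t-1} - mu) + N(0, sig2z),
//              Z_1 ~ N(mu, sig2z / (1 - rho^2))  (stationary start).
// Observation: ybar_t ~ N(Z_t, 1 / obs_prec_t) where ybar_t is the mean of
//              the site-adjusted log observations on day t and obs_prec_t =
//              n_t / sig2eps (0 when the day has no observations; ybar is
//              then ignored).
//
// Returns one exact joint draw of the whole path from its full conditional,
// using R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector ffbs_ar1(NumericVector ybar, NumericVector obs_prec,
                       double mu, double rho, double sig2z) {
  int T = ybar.size();
  if (obs_prec.size() != T) stop("ybar and obs_prec lengths differ");
  if (sig2z <= 0) stop("sig2z must be positive");
  if (rho <= -1.0 || rho >= 1.0) stop("|rho| must be < 1");
  NumericVector f(T), F(T), z(T);

  double a = mu;
  double P = sig2z / (1.0 - rho * rho);
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      a = mu + rho * (f[t - 1] - mu);
      P = rho * rho * F[t - 1] + sig2z;
    }
    double prec = 1.0 / P + obs_prec[t];
    if (!R_finite(prec) || prec <= 0)
      stop("non-finite filter precision at t=%d (degenerate variances)", t + 1);
    F[t] = 1.0 / prec;
    double h = a / P;
    if (obs_prec[t] > 0) h += obs_prec[t] * ybar[t];
    f[t] = F[t] * h;
    if (!R_finite(f[t])) stop("non-finite filter mean at t=%d", t + 1);
  }

  z[T - 1] = R::rnorm(f[T - 1], sqrt(F[T - 1]));
  for (int t = T - 2; t >= 0; --t) {
    double prec = 1.0 / F[t] + rho * rho / sig2z;
    double var = 1.0 / prec;
    double mean = var * (f[t] / F[t] +
                         rho * (z[t + 1] - mu * (1.0 - rho)) / sig2z);
    z[t] = R::rnorm(mean, sqrt(var));
  }
  return z;
}
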