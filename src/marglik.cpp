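#include <Rcpp.h>
using namespace Rcpp;

// Truncated Poisson-Gaussian marginal log-likelihood and count-posterior moments.
//
// For each matrix entry (neuron i, bin t) evaluates
//   ll = log sum_{n=0..R} N(delta; c_i n, sigma2_i) Poisson(n; lambda)
// in log space (log-sum-exp), including the Gaussian normalizer, together with
// the posterior moments E[n | delta, lambda] and E[n^2 | delta, lambda] of the
// truncated count posterior. The moments make every downstream update
// closed-form: rate gradients (E[n]/lambda - 1), influx/AR/noise updates in the
// ECM M-step, and reparameterized ELBO gradients.
//
// lambda == 0 is treated as a point mass at n = 0 (exactly the Gaussian term).
// [[Rcpp::export(name = ".calcium_marglik_cpp")]]
List calcium_marglik_cpp(NumericMatrix delta, NumericMatrix lambda,
                         NumericVector cvec, NumericVector sigma2,
                         int max_count, bool moments) {
  const int N = delta.nrow(), T = delta.ncol(), R = max_count;
  if (lambda.nrow() != N || lambda.ncol() != T)
    stop("rate matrix shape does not match residual matrix");
  NumericMatrix ll(N, T), en, en2;
  if (moments) { en = NumericMatrix(N, T); en2 = NumericMatrix(N, T); }
  std::vector<double> lt(R + 1), lgam(R + 1);
  for (int n = 0; n <= R; ++n) lgam[n] = R::lgammafn(n + 1.0);
  for (int i = 0; i < N; ++i) {
    const double c = cvec[i], s2 = sigma2[i];
    const double lnorm = -0.5 * std::log(2.0 * M_PI * s2);
    const double inv2s2 = 1.0 / (2.0 * s2);
    for (int t = 0; t < T; ++t) {
      const double d = delta(i, t), lam = lambda(i, t);
      if (!(lam > 0.0)) {  // point mass at n = 0
        ll(i, t) = lnorm - d * d * inv2s2;
        continue;
      }
      const double llam = std::log(lam);
      double m = R_NegInf;
      for (int n = 0; n <= R; ++n) {
        const double r = d - c * n;
        lt[n] = -r * r * inv2s2 + n * llam - lgam[n] - lam;
        if (lt[n] > m) m = lt[n];
      }
      double se = 0.0, s1 = 0.0, s2m = 0.0;
      for (int n = 0; n <= R; ++n) {
        const double a = lt[n] - m;
        if (a < -700.0) continue;  // negligible, and subnormal exp() is slow
        const double w = std::exp(a);
        se += w;
        if (moments) { s1 += n * w; s2m += double(n) * n * w; }
      }
      ll(i, t) = lnorm + m + std::log(se);
      if (moments) { en(i, t) = s1 / se; en2(i, t) = s2m / se; }
    }
  }
  if (moments) return List::create(_["ll"] = ll, _["en"] = en, _["en2"] = en2);
  return List::create(_["ll"] = ll);
}

// Generate an AR(p) fluorescence trace from integer spike counts:
//   y_t = sum_i alpha_i y_{t-i} + c s_t + process noise (already in eps).
// eps carries the N(0, sigma2) process-noise draws so that the R caller owns
// the random number stream; lags before t = 1 are zero.
// [[Rcpp::export(name = ".ar_filter_spikes_cpp")]]
NumericMatrix ar_filter_spikes_cpp(IntegerMatrix spikes, NumericMatrix alphas,
                                   NumericVector cvec, NumericMatrix eps) {
  const int N = spikes.nrow(), T = spikes.ncol(), p = alphas.ncol();
  NumericMatrix y(N, T);
  for (int i = 0; i < N; ++i) {
    for (int t = 0; t < T; ++t) {
      double v = cvec[i] * spikes(i, t) + eps(i, t);
      for (int j = 0; j < p; ++j)
        if (t - 1 - j >= 0) v += alphas(i, j) * y(i, t - 1 - j);
      y(i, t) = v;
    }
  }
  return y;
}
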