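# Small fixtures shared across test files, built in code.

# Naive R-level evaluation of the truncated Poisson-Gaussian marginal:
# the independent oracle for the compiled kernel.
naive_marglik <- function(delta, lambda, cc, s2, R) {
  out <- delta
  for (i in seq_len(nrow(delta))) for (t in seq_len(ncol(delta))) {
    terms <- stats::dnorm(delta[i, t], cc[i] * 0:R, sqrt(s2[i])) *
      stats::dpois(0:R, lambda[i, t])
    out[i, t] <- log(sum(terms))
  }
  out
}

# Short single-neuron trace with one clean transient.
toy_trace <- function() {
  cp <- calcium_params(alphas = 0.8, c = 1, sigma2 = 0.01)
  sp <- matrix(0, 1, 20); sp[1, 5] <- 1; sp[1, 13] <- 2
  list(params = cp, spikes = sp,
       y = sample_trace(sp, cp, seed = 42))
}

# Enumerate all K^T state paths of a tiny HMM; returns exact logZ, posterior
# marginals and the most likely path.
enumerate_hmm <- function(loglik, pi0, P) {
  T <- nrow(loglik); K <- ncol(loglik)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1L, function(z) {
    v <- log(pi0[z[1L]]) + loglik[1L, z[1L]]
    for (t in seq_len(T - 1L))
      v <- v + log(P[z[t], z[t + 1L]]) + loglik[t + 1L, z[t + 1L]]
    v
  })
  logZ <- max(lp) + log(sum(exp(lp - max(lp))))
  w <- exp(lp - logZ)
  gamma <- matrix(0, T, K)
  for (t in seq_len(T)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k])
  list(logZ = logZ, gamma = gamma,
       map = paths[which.max(lp), ])
}
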