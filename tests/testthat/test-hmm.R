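test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(10)
  for (case in 1:3) {
    K <- 2; T <- 5
    ll <- matrix(rnorm(T * K), T, K)
    pi0 <- c(0.3, 0.7)
    P <- matrix(c(0.8, 0.2, 0.35, 0.65), 2, byrow = TRUE)
    fb <- forward_backward(ll, pi0, P)
    ref <- enumerate_hmm(ll, pi0, P)
    expect_equal(fb$logZ, ref$logZ, tolerance = 1e-10)
    expect_equal(fb$gamma, ref$gamma, tolerance = 1e-8)
    expect_equal(rowSums(fb$gamma), rep(1, T), tolerance = 1e-12)
  }
})

test_that("forward-backward degenerate cases behave", {
  # K = 1: gamma is all ones and logZ sums the emissions
  ll <- matrix(rnorm(6), 6, 1)
  fb <- forward_backward(ll, 1, matrix(1, 1, 1))
  expect_equal(drop(fb$gamma), rep(1, 6))
  expect_equal(fb$logZ, sum(ll))

  # uninformative emissions: posteriors equal the chain marginals
  P <- matrix(c(0.9, 0.1, 0.4, 0.6), 2, byrow = TRUE)
  pi0 <- c(1, 0)
  fb2 <- forward_backward(matrix(0, 4, 2), pi0, P)
  marg <- pi0
  for (t in 1:4) {
    expect_equal(fb2$gamma[t, ], marg, tolerance = 1e-12)
    marg <- drop(marg %*% P)
  }

  expect_error(forward_backward(matrix(-Inf, 3, 2), c(0.5, 0.5),
                                matrix(0.5, 2, 2)),
               "numerical failure")

  # trial-structured logZ is the sum of per-trial logZ
  ll3 <- matrix(rnorm(12), 6, 2)
  fb_all <- forward_backward(ll3, c(0.5, 0.5), P, trial_ids = rep(1:2, each = 3))
  fb_a <- forward_backward(ll3[1:3, ], c(0.5, 0.5), P)
  fb_b <- forward_backward(ll3[4:6, ], c(0.5, 0.5), P)
  expect_equal(fb_all$logZ, fb_a$logZ + fb_b$logZ)
})

test_that("Viterbi matches exhaustive argmax and follows chains", {
  set.seed(11)
  K <- 2; T <- 6
  ll <- matrix(rnorm(T * K), T, K)
  pi0 <- c(0.6, 0.4)
  P <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE)
  path <- calatent:::viterbi_path(ll, pi0, P)
  ref <- enumerate_hmm(ll, pi0, P)
  expect_equal(path, unname(ref$map))

  # K = 1 gives a constant path
  expect_equal(calatent:::viterbi_path(matrix(rnorm(5), 5, 1), 1,
                                       matrix(1, 1, 1)),
               rep(1L, 5))

  # deterministic cyclic transitions with unambiguous emissions
  K <- 3
  Pc <- matrix(0, K, K); for (k in 1:K) Pc[k, k %% K + 1] <- 1
  llc <- matrix(-50, 9, K)
  llc[cbind(1:9, rep(c(2, 3, 1), 3))] <- 0
  expect_equal(calatent:::viterbi_path(llc, c(0, 1, 0), Pc),
               rep(c(2, 3, 1), 3))
})

test_that("emission log-likelihoods reduce to the marginal likelihood", {
  tt <- toy_trace()
  # K = 1: the single column equals the summed per-bin marginal
  model <- list(obs = "calcium", K = 1L, rates = matrix(0.3, 1, 1),
                obs_params = tt$params, alpha_clip = c(0.6, 0.95),
                max_count = 15L)
  ll <- calatent:::hmm_emission_logliks(tt$y, model)
  ref <- calcium_loglik(tt$y, 0.3, tt$params, max_count = 15)
  expect_equal(drop(ll), colSums(ref$per_bin), tolerance = 1e-12)

  # identical rates in two states give identical columns
  model2 <- model; model2$K <- 2L; model2$rates <- matrix(0.3, 2, 1)
  ll2 <- calatent:::hmm_emission_logliks(tt$y, model2)
  expect_equal(ll2[, 1], ll2[, 2])

  # K = 2, N = 1, T = 4: direct evaluation of the truncated mixture per state
  y4 <- trace_set(tt$y$values[, 1:4, drop = FALSE])
  model3 <- model2; model3$rates <- matrix(c(0.1, 1.2), 2, 1)
  ll3 <- calatent:::hmm_emission_logliks(y4, model3)
  d4 <- ar_residual(y4, tt$params)
  for (k in 1:2) {
    ref_k <- naive_marglik(d4, matrix(model3$rates[k, 1], 1, 4),
                           tt$params$c, tt$params$sigma2, 15)
    expect_equal(ll3[, k], drop(ref_k), tolerance = 1e-10)
  }
})

test_that("EM increases the likelihood and recovers separated rates", {
  set.seed(12)
  # two well-separated states, five neurons
  K <- 2; N <- 5; T <- 2000
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  rates <- rbind(rep(0.05, N), rep(1.0, N))
  obs <- calcium_params(alphas = rep(0.8, N), c = 1, sigma2 = 0.01)
  states <- integer(T); states[1] <- 1
  for (t in 1:(T - 1)) states[t + 1] <- sample.int(2, 1, prob = P[states[t], ])
  lam <- t(rates[states, ])
  spikes <- matrix(rpois(N * T, lam), N, T)
  y <- sample_trace(spikes, obs)

  fit <- calcium_hmm(y, K = 2, obs = "calcium", n_iter = 40, restarts = 2,
                     seed = 1)
  al <- align_states(states, fit$states, K = 2)
  expect_gt(al$agreement, 0.9)
  # the identifiable emission scale is the calcium influx c * lambda;
  # per-state mean rates recover within 15% (the 0.05 state has only
  # ~50 expected spikes per neuron, so per-neuron error is noise-limited)
  influx_hat <- fit$rates * rep(fit$obs_params$c, each = 2)
  influx_hat <- influx_hat[order(rowMeans(influx_hat)), ]
  expect_lt(max(abs(rowMeans(influx_hat) - c(0.05, 1)) / c(0.05, 1)), 0.15)

  # warm start at the truth: likelihood does not decrease
  fit0 <- calcium_hmm(y, K = 2, obs = "calcium", n_iter = 10, tol = 0,
                      init = list(pi0 = c(0.5, 0.5), P = P, rates = rates,
                                  obs_params = obs))
  expect_true(all(diff(fit0$loglik_trace) > -1e-6 * abs(fit0$loglik)))
  # and every fit's training trace is monotone up to tolerance
  expect_true(all(diff(fit$loglik_trace) > -1e-4 * abs(fit$loglik)))
})

test_that("posterior marginals are stable under state relabeling", {
  tt <- toy_trace()
  set.seed(13)
  ll <- matrix(rnorm(20 * 3), 20, 3)
  pi0 <- c(0.2, 0.3, 0.5)
  P <- matrix(c(0.8, 0.1, 0.1, 0.2, 0.6, 0.2, 0.3, 0.3, 0.4), 3, byrow = TRUE)
  perm <- c(3, 1, 2)
  fb <- forward_backward(ll, pi0, P)
  fb_p <- forward_backward(ll[, perm], pi0[perm], P[perm, perm])
  expect_equal(fb_p$gamma, fb$gamma[, perm], tolerance = 1e-10)
  expect_equal(fb_p$logZ, fb$logZ, tolerance = 1e-10)
})

test_that("state-number selection returns the requested degenerate case", {
  set.seed(14)
  sim <- simulate_chain_hmm(n_states = 2, neurons_per_state = 2,
                            n_time = 300, seed = 2)
  sel <- select_num_states(sim$train, sim$test, K_range = 2,
                           obs = "gaussian", n_iter = 10, restarts = 1,
                           seed = 1)
  expect_equal(sel$best_K, 2)
  expect_equal(nrow(sel$table), 1)
})

test_that("occupancy statistics recover peak and width geometrically", {
  # rectangular occupancy: 10 bins at dt = 0.5 starting at bin 41
  paths <- matrix(1L, 20, 100)
  paths[, 41:50] <- 2L
  oc <- occupancy_stats(paths, 2, dt = 0.5)
  expect_gte(oc$peak_time, 20); expect_lt(oc$peak_time, 25)
  expect_equal(oc$width, 5, tolerance = 1e-9)

  # single trial: occupancy is 0/1 and FWHM is the block length
  p1 <- matrix(1L, 1, 50); p1[1, 11:22] <- 2L
  oc1 <- occupancy_stats(p1, 2, dt = 1)
  expect_true(all(oc1$curve %in% c(0, 1)))
  expect_equal(oc1$width, 12, tolerance = 1 + 1e-9)

  # triangular profile: FWHM is half the base
  base <- 40
  tri <- c(seq(0, 1, length.out = base / 2), seq(1, 0, length.out = base / 2))
  paths_tri <- matrix(1L, 200, base)
  for (b in seq_len(base)) paths_tri[seq_len(round(200 * tri[b])), b] <- 2L
  oc2 <- occupancy_stats(paths_tri, 2, dt = 1)
  expect_equal(oc2$width, base / 2, tolerance = 0.15)

  expect_error(occupancy_stats(matrix(1L, 3, 10), 2), "never visited")
})

test_that("fitted HMM objects support the standard methods", {
  set.seed(15)
  sim <- simulate_chain_hmm(n_states = 2, neurons_per_state = 2,
                            n_time = 200, seed = 3)
  fit <- calcium_hmm(sim$train, K = 2, n_iter = 8, restarts = 1, seed = 1)
  expect_s3_class(fit, "calcium_hmm")
  expect_output(print(fit), "calcium_hmm")
  expect_equal(length(predict(fit, type = "states")), 200)
  expect_equal(dim(predict(fit, newdata = sim$test, type = "gamma")),
               c(200, 2))
  expect_type(logLik(fit)[1], "double")
  expect_named(coef(fit), c("pi0", "P", "rates", "obs_params"))
  simd <- simulate(fit, nsim = 50, seed = 1)
  expect_equal(dim(simd$y$values), c(4, 50))
})
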