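test_that("AR residual matches the lag-sum definition", {
  # exact AR(1) prediction: y = (1, alpha) gives delta = (1, 0)
  cp <- calcium_params(alphas = 0.7, c = 1, sigma2 = 0.01)
  d <- ar_residual(matrix(c(1, 0.7), 1), cp)
  expect_equal(drop(d), c(1, 0))

  expect_equal(ar_residual(matrix(0, 2, 6),
                           calcium_params(c(0.8, 0.9))),
               matrix(0, 2, 6))

  # random 3-neuron AR(2) trace against an element-wise loop
  set.seed(7)
  y <- matrix(rnorm(150), 3, 50)
  al <- cbind(runif(3, 0.5, 1.2), runif(3, -0.4, 0))
  cp2 <- calcium_params(al, c = 1, sigma2 = 0.01)
  d2 <- ar_residual(y, cp2)
  ref <- y
  for (i in 1:3) for (t in 1:50) {
    ref[i, t] <- y[i, t] -
      al[i, 1] * (if (t > 1) y[i, t - 1] else 0) -
      al[i, 2] * (if (t > 2) y[i, t - 2] else 0)
  }
  expect_equal(d2, ref, tolerance = 1e-12)

  expect_error(ar_residual(matrix(c(1, NA), 1), cp), "finite")
})

test_that("residuals restart at trial boundaries", {
  cp <- calcium_params(alphas = 0.9, c = 1, sigma2 = 0.01)
  y <- trace_set(matrix(c(1, 0.9, 1, 0.9), 1), trial_ids = c(1, 1, 2, 2))
  expect_equal(drop(ar_residual(y, cp)), c(1, 0, 1, 0))
})

test_that("marginal likelihood matches brute-force summation", {
  set.seed(3)
  N <- 2; T <- 8
  cp <- calcium_params(alphas = c(0.8, 0.85), c = c(1, 1.3),
                       sigma2 = c(0.01, 0.05))
  y <- matrix(rnorm(N * T, 0, 0.8), N, T)
  lam <- matrix(runif(N * T, 0.05, 2), N, T)
  ml <- calcium_loglik(y, lam, cp, max_count = 25)
  ref <- naive_marglik(ar_residual(y, cp), lam, cp$c, cp$sigma2, 25)
  expect_lt(max(abs(ml$per_bin - ref)), 1e-10)
  expect_equal(ml$total, sum(ref))

  # single-bin case with the exact mixture summed term by term
  cp1 <- calcium_params(0, c = 1, sigma2 = 0.01)
  v <- calcium_loglik(matrix(c(0, 1), 1), matrix(c(0, 1.5), 1), cp1,
                      max_count = 20)$per_bin[1, 2]
  bf <- log(sum(dnorm(1, 0:20, 0.1) * dpois(0:20, 1.5)))
  expect_equal(v, bf, tolerance = 1e-12)
})

test_that("zero-rate and vanishing-influx limits are exact", {
  cp <- calcium_params(alphas = 0.8, c = 1, sigma2 = 0.01)
  y <- matrix(c(0.2, 0.5, 0.1, 0.4), 1)
  d <- ar_residual(y, cp)
  # lambda = 0: only the zero-count term survives
  v0 <- calcium_loglik(y, matrix(0, 1, 4), cp)$per_bin
  expect_equal(v0, dnorm(d, 0, 0.1, log = TRUE), tolerance = 1e-12)
  # c -> 0: likelihood loses all dependence on the rate
  cps <- calcium_params(alphas = 0.8, c = 1e-10, sigma2 = 0.01)
  va <- calcium_loglik(y, matrix(0.5, 1, 4), cps)$per_bin
  vb <- calcium_loglik(y, matrix(3.0, 1, 4), cps, max_count = 40)$per_bin
  expect_equal(va, dnorm(ar_residual(y, cps), 0, 0.1, log = TRUE),
               tolerance = 1e-6)
  expect_equal(va, vb, tolerance = 1e-6)
})

test_that("truncation converges once R passes the Poisson bulk", {
  set.seed(4)
  cp <- calcium_params(alphas = 0.8, c = 1, sigma2 = 0.01)
  y <- matrix(rnorm(30, 0, 1), 1)
  lam <- matrix(runif(30, 0.1, 3), 1)
  R0 <- ceiling(max(lam) + 10 * sqrt(max(lam)) + max(abs(y)))
  a <- calcium_loglik(y, lam, cp, max_count = R0)$per_bin
  b <- calcium_loglik(y, lam, cp, max_count = R0 + 10)$per_bin
  expect_lt(max(abs(a - b)), 1e-10)
  # too-small truncation at large rates warns with the discarded mass
  expect_warning(calcium_loglik(y, matrix(30, 1, 30), cp, max_count = 5),
                 "tail mass")
})

test_that("the marginal is a proper density in the residual", {
  cp <- calcium_params(alphas = 0, c = 1, sigma2 = 0.04)
  grid <- seq(-4, 8, by = 1e-3)
  y <- matrix(grid, 1)  # alpha = 0 so delta equals y
  ll <- calcium_loglik(y, matrix(0.8, 1, length(grid)), cp,
                       max_count = 20)$per_bin
  expect_equal(sum(exp(ll)) * 1e-3, 1, tolerance = 1e-4)
})

test_that("log-likelihood is equivariant under joint rescaling", {
  set.seed(5)
  cp <- calcium_params(alphas = 0.8, c = 1.2, sigma2 = 0.02)
  y <- matrix(rnorm(40, 0, 1), 1)
  lam <- matrix(0.4, 1, 40)
  s <- 3.7
  cps <- calcium_params(alphas = 0.8, c = 1.2 * s, sigma2 = 0.02 * s^2)
  l1 <- calcium_loglik(y, lam, cp, max_count = 20)$per_bin
  l2 <- calcium_loglik(s * y, lam, cps, max_count = 20)$per_bin
  expect_equal(l2, l1 - log(s), tolerance = 1e-10)
})

test_that("sampled traces follow the noiseless impulse response", {
  sp <- matrix(0, 1, 12); sp[1, 5] <- 1
  cp <- calcium_params(alphas = 0.8, c = 1.3, sigma2 = 1e-30)
  tr <- sample_trace(sp, cp, seed = 1)
  expect_equal(tr$values[1, 1:4], rep(0, 4))
  expect_equal(tr$values[1, 5:12], 1.3 * 0.8^(0:7), tolerance = 1e-9)
  expect_equal(sample_trace(matrix(0L, 2, 6),
                            calcium_params(c(0.8, 0.9), sigma2 = 1e-30),
                            seed = 1)$values,
               matrix(0, 2, 6), tolerance = 1e-14)
})

test_that("innovation moments match the Poisson-Gaussian mixture", {
  set.seed(6)
  Tn <- 1e5; lam <- 0.25
  cp <- calcium_params(alphas = 0.85, c = 1.1, sigma2 = 0.02)
  sp <- matrix(rpois(Tn, lam), 1)
  tr <- sample_trace(sp, cp)
  d <- drop(ar_residual(tr, cp))[-1]
  m_exp <- 1.1 * lam
  v_exp <- 1.1^2 * lam + 0.02
  se_m <- sqrt(v_exp / Tn)
  expect_lt(abs(mean(d) - m_exp), 3 * se_m)
  # variance standard error for the mixture (loose normal-theory bound)
  expect_lt(abs(var(d) - v_exp), 4 * v_exp / sqrt(Tn) * 3)
})

test_that("heuristic initialization recovers decay and influx", {
  # noiseless AR(1) decay: exact linear relation
  y <- matrix(2 * 0.9^(0:49), 1)
  p <- suppressWarnings(init_neuron_params(y))
  expect_equal(p$alphas[1, 1], 0.9, tolerance = 1e-8)

  # isolated jumps of sizes {c, 2c} with small noise: c within a grid step
  set.seed(8)
  sp <- matrix(0, 1, 400)
  sp[1, seq(10, 390, by = 20)] <- rep(c(1L, 1L, 2L), length.out = 20)
  cp <- calcium_params(alphas = 0.7, c = 1.2, sigma2 = 1e-4)
  tr <- sample_trace(sp, cp)
  est <- init_neuron_params(tr)
  expect_lt(abs(est$c[1] - 1.2), 0.011 + 1e-9)

  # default grid endpoints of the influx sweep
  grid_default <- eval(formals(init_neuron_params)$c_grid)
  expect_equal(range(grid_default), c(0.8, 2.2))

  # constant trace falls back to defaults with a warning
  expect_warning(p0 <- init_neuron_params(matrix(1, 1, 100)), "degenerate")
  expect_equal(p0$alphas[1, 1], 0.8)
  expect_equal(p0$c[1], 1.0)
})
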