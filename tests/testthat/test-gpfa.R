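test_that("RBF Gram matrix matches the closed form and is PSD", {
  K <- rbf_gram(1:5, lengthscale = 2, jitter = 1e-8)
  expect_equal(K[1, 1], 1 + 1e-8)
  expect_equal(K[2, 4], exp(-4 / 8), tolerance = 1e-12)
  # half-covariance separation: |t - t'| = l * sqrt(2 log 2)
  l <- 3
  tsep <- l * sqrt(2 * log(2))
  K2 <- rbf_gram(c(0, tsep), l, jitter = 0)
  expect_equal(K2[1, 2], 0.5, tolerance = 1e-12)
  # elementwise oracle on a grid, and a successful Cholesky
  g <- seq_len(5)
  K3 <- rbf_gram(g, 2)
  ref <- exp(-outer(g, g, "-")^2 / 8) + 1e-5 * diag(5)
  expect_equal(K3, ref, ignore_attr = TRUE, tolerance = 1e-12)
  expect_silent(chol(K3))
  # eigenvalues before jitter stay above -1e-8 on longer grids
  ev <- eigen(exp(-outer(1:500, 1:500, "-")^2 / (2 * 50^2)),
              symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_error(rbf_gram(1:4, -1), "lengthscale")
})

test_that("the factored KL to the GP prior is nonnegative and exact", {
  set.seed(30)
  T <- 40
  prior <- calatent:::gp_prior_struct(T, 8)[[1]]
  K <- rbf_gram(seq_len(T), 8)
  for (case in 1:5) {
    m <- rnorm(T, 0, 0.5); v <- exp(rnorm(T, -1, 0.5))
    kl <- calatent:::gp_kl(m, v, prior)$kl
    # direct Gaussian KL between N(m, diag v) and N(0, K)
    ref <- 0.5 * (sum(diag(solve(K) %*% diag(v))) + t(m) %*% solve(K) %*% m -
                    T + as.numeric(determinant(K)$modulus) - sum(log(v)))
    expect_equal(kl, drop(ref), tolerance = 1e-8, ignore_attr = TRUE)
    expect_gte(kl, 0)
  }
  # T = 1: the diagonal family contains the prior, so the KL can reach 0
  p1 <- calatent:::gp_prior_struct(1, 5)[[1]]
  expect_equal(calatent:::gp_kl(0, 1 + 1e-5, p1)$kl, 0, tolerance = 1e-10)
})

test_that("the ELBO lower-bounds a quadrature marginal likelihood", {
  # tiny model: 1 latent, 3 bins, 1 neuron; integrate the 3-dim latent
  set.seed(31)
  cp <- calcium_params(alphas = 0.8, c = 1, sigma2 = 0.04)
  yv <- matrix(c(0.1, 0.9, 0.6), 1)
  y <- trace_set(yv)
  Kg <- rbf_gram(1:3, 2, jitter = 1e-6)
  C <- matrix(0.8, 1, 1); d <- -0.5
  loglik_x <- function(x) {
    rate <- matrix(calatent:::softplus(C[1, 1] * x + d), 1)
    calcium_loglik(y, rate, cp, max_count = 25)$total
  }
  gr <- seq(-5, 5, length.out = 41)
  h <- gr[2] - gr[1]
  # dense quadrature over the 3-bin latent; the likelihood factorizes over
  # bins, so tabulate each bin's likelihood on the grid once
  Ltab <- vapply(gr, function(g) {
    rate <- matrix(calatent:::softplus(C[1, 1] * g + d), 1, 3)
    exp(calcium_loglik(y, rate, cp, max_count = 25)$per_bin[1, ])
  }, numeric(3))          # 3 x length(gr)
  G <- as.matrix(expand.grid(gr, gr, gr))
  Kinv <- solve(Kg)
  pr <- exp(-0.5 * rowSums((G %*% Kinv) * G)) / sqrt((2 * pi)^3 * det(Kg))
  lik <- Ltab[1, match(G[, 1], gr)] * Ltab[2, match(G[, 2], gr)] *
    Ltab[3, match(G[, 3], gr)]
  logml <- log(sum(pr * lik) * h^3)
  prior <- calatent:::gp_prior_struct(3, 2, jitter = 1e-6)
  for (case in 1:20) {
    m <- rnorm(3, 0, 1); v <- exp(rnorm(3, -0.5, 0.5))
    kl <- calatent:::gp_kl(m, v, prior[[1]])$kl
    ell <- mean(replicate(200, loglik_x(m + sqrt(v) * rnorm(3))))
    # allow Monte Carlo slack of a few standard errors on the bound
    expect_lt(ell - kl, drop(logml) + 0.15)
  }
})

test_that("ELBO estimates are seed-reproducible with shrinking MC variance", {
  set.seed(32)
  sim <- simulate_gp_latents(n_neurons = 4, n_time = 60,
                             lengthscales = c(10, 15), seed = 1)
  fit <- calcium_gpfa(sim$y, n_latents = 2, ar_order = 2, lengthscale = 12,
                      n_iter = 30, seed = 1)
  e1 <- gpfa_elbo(fit, n_mc = 5, seed = 99)
  e2 <- gpfa_elbo(fit, n_mc = 5, seed = 99)
  expect_identical(e1, e2)
  v <- vapply(c(1, 10, 100), function(nm)
    var(vapply(1:40, function(i) gpfa_elbo(fit, n_mc = nm, seed = i),
               numeric(1))), numeric(1))
  # variance drops roughly like 1/n_mc (allow wide stochastic slack)
  expect_gt(v[1] / v[3], 20)
})

test_that("variational fitting recovers a one-dimensional latent", {
  set.seed(33)
  sim <- simulate_gp_latents(n_neurons = 10, n_time = 500,
                             lengthscales = 40, ar_order = 1,
                             mean_rate = 0.3, loading_sd = 0.8,
                             measurement_noise_sd = 0.1, seed = 2)
  fit <- calcium_gpfa(sim$y, n_latents = 1, ar_order = 1, lengthscale = 40,
                      n_iter = 1200, seed = 3)
  al <- align_latents(sim$latents, predict(fit))
  expect_gt(al$mean_r2, 0.8)
  # smoothed ELBO should improve over training
  n <- length(fit$elbo_trace)
  expect_gt(mean(fit$elbo_trace[(n - 100):n]),
            mean(fit$elbo_trace[1:100]))
})

test_that("GPFA handles baseline observation models and bad input", {
  set.seed(34)
  sim <- simulate_gp_latents(n_neurons = 4, n_time = 80,
                             lengthscales = c(10, 12), seed = 4)
  fg <- calcium_gpfa(sim$y, n_latents = 2, obs = "gaussian",
                     lengthscale = 10, n_iter = 40, seed = 1)
  expect_s3_class(fg, "calcium_gpfa")
  expect_equal(dim(predict(fg)), c(2, 80))
  # Poisson-observation variant runs on (deconvolved or true) spike counts
  fp <- calcium_gpfa(sim$spikes, n_latents = 2, obs = "poisson",
                     lengthscale = 10, n_iter = 40, seed = 1)
  expect_s3_class(fp, "calcium_gpfa")
  expect_warning(calcium_gpfa(matrix(0, 3, 40), n_latents = 1,
                              obs = "poisson", lengthscale = 10,
                              n_iter = 2, seed = 1), "all-zero")
  expect_error(calcium_gpfa(sim$spikes - 1, n_latents = 1, obs = "poisson",
                            lengthscale = 10, n_iter = 2), "nonnegative")
})
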