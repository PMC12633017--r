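# A tiny fitted object used as a carrier for rollout/ELBO property checks.
tiny_lfads <- function(obs = "calcium", seed = 50, epochs = 1) {
  set.seed(seed)
  sim <- simulate_lorenz(n_trials = 6, trial_len = 15, n_neurons = 5,
                         seed = seed)
  calcium_lfads(sim$y, gen_dim = 4, encoder_dim = 6, controller_dim = 4,
                obs = obs, epochs = epochs, batch_size = 6, kl_warmup = 5,
                seed = seed)
}

test_that("generative rollout obeys closed-form degenerate cases", {
  fit <- tiny_lfads()
  th <- fit$theta
  # zero readout weights with d = log r: constant rate r everywhere
  th$C[] <- 0; th$d[] <- log(0.7)
  fit$theta <- th
  ro <- lfads_rollout(fit, x0 = matrix(0, 2, 4),
                      u = array(0, c(2, 1, 10)), seed = 1)
  expect_equal(as.vector(ro$rates), rep(0.7, 2 * 5 * 10), tolerance = 1e-12)
  # zero input, zero initial state: the all-zero GRU fixed point holds
  # (zero biases keep the candidate at tanh(0) = 0)
  th$gen$b[] <- 0; fit$theta <- th
  ro2 <- lfads_rollout(fit, x0 = matrix(0, 1, 4),
                       u = array(0, c(1, 1, 8)), seed = 1)
  expect_equal(max(abs(ro2$factors)), 0)
  # sampled spikes at fixed rates have Poisson mean ~ variance
  ro3 <- lfads_rollout(fit, x0 = matrix(0, 100, 4),
                       u = array(0, c(100, 1, 100)), seed = 2)
  s <- as.vector(ro3$spikes)
  expect_equal(mean(s), 0.7, tolerance = 0.02)
  expect_equal(var(s), 0.7, tolerance = 0.04)
})

test_that("GRU backpropagation matches numerical gradients", {
  set.seed(51)
  par <- gru <- calatent:::gru_params(2, 3)
  X <- array(rnorm(4 * 2 * 5), c(4, 2, 5))
  h0 <- matrix(rnorm(12), 4, 3)
  loss <- function(p) {
    fw <- calatent:::gru_forward(p, X, h0)
    sum(fw$h^2) / 2
  }
  fw <- calatent:::gru_forward(par, X, h0)
  bw <- calatent:::gru_backward(par, fw$cache, fw$h)
  eps <- 1e-6
  for (nm in c("Wx", "Urz", "Un", "b")) {
    for (idx in sample(length(par[[nm]]), 4)) {
      pp <- par; pp[[nm]][idx] <- pp[[nm]][idx] + eps
      pm <- par; pm[[nm]][idx] <- pm[[nm]][idx] - eps
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(bw$grads[[nm]][idx], num, tolerance = 1e-4)
    }
  }
  # input and initial-state gradients
  for (idx in sample(length(X), 3)) {
    Xp <- X; Xp[idx] <- Xp[idx] + eps
    Xm <- X; Xm[idx] <- Xm[idx] - eps
    fwp <- calatent:::gru_forward(par, Xp, h0)
    fwm <- calatent:::gru_forward(par, Xm, h0)
    num <- (sum(fwp$h^2) - sum(fwm$h^2)) / (4 * eps)
    expect_equal(bw$dX[idx], num, tolerance = 1e-4)
  }
})

test_that("the full ELBO gradient matches finite differences", {
  set.seed(52)
  sim <- simulate_lorenz(n_trials = 3, trial_len = 8, n_neurons = 4, seed = 1)
  Y <- calatent:::trials_array(sim$y)
  cfg <- list(N = 4, T = 8, g = 3, He = 4, Hc = 3, U = 1, obs = "calcium",
              sic2 = 1, a = 0.9, b = 0, su2 = 0.1, max_count = 8,
              rate_guess = 0.4)
  obs_init <- calcium_params(rep(0.85, 4), c = rep(1, 4), sigma2 = rep(0.05, 4))
  th <- calatent:::lfads_init_theta(cfg, obs_init)
  # the objective is stochastic: fix the RNG per evaluation
  obj <- function(theta) {
    set.seed(99)
    calatent:::lfads_step(theta, Y, cfg, kl_weight = 0.7,
                          want_grads = FALSE)$obj
  }
  set.seed(99)
  st <- calatent:::lfads_step(th, Y, cfg, kl_weight = 0.7)
  flat <- calatent:::flatten_params(th)
  gflat <- calatent:::flatten_params(st$grads)
  eps <- 1e-5
  for (nm in c("gen.Wx", "ctrl.Un", "enc_f.Urz", "enc_b.Wx", "W_ic", "W_u",
               "C", "d", "alpha", "logc", "logs2", "b_u")) {
    for (idx in sample(length(flat[[nm]]), 2)) {
      fp <- flat; fp[[nm]][idx] <- fp[[nm]][idx] + eps
      fm <- flat; fm[[nm]][idx] <- fm[[nm]][idx] - eps
      num <- (obj(calatent:::unflatten_params(fp)) -
                obj(calatent:::unflatten_params(fm))) / (2 * eps)
      expect_equal(gflat[[nm]][idx], num, tolerance = 2e-3,
                   label = sprintf("grad %s[%d]", nm, idx))
    }
  }
})

test_that("KL terms are nonnegative and removing them raises the objective", {
  fit <- tiny_lfads(epochs = 2)
  e1 <- lfads_elbo(fit, kl_weight = 1, seed = 7)
  e0 <- lfads_elbo(fit, kl_weight = 0, seed = 7)
  expect_gte(e1$kl, 0)
  expect_gte(e0$objective, e1$objective)
})

test_that("a small model overfits a few trials (smoothed ELBO rises)", {
  set.seed(53)
  sim <- simulate_lorenz(n_trials = 4, trial_len = 20, n_neurons = 6, seed = 2)
  fit <- calcium_lfads(sim$y, gen_dim = 8, encoder_dim = 8,
                       controller_dim = 6, obs = "calcium", epochs = 200,
                       batch_size = 4, kl_warmup = 50, lr = 5e-3, seed = 3)
  tr <- fit$elbo_trace
  n <- length(tr)
  expect_gt(mean(tr[(n - 40):n]), mean(tr[1:40]))
})

test_that("calcium head initialization recovers decay and influx", {
  set.seed(54)
  # noiseless traces with isolated spikes: exact recovery
  cp <- calcium_params(alphas = 0.9, c = 1.2, sigma2 = 1e-30)
  sp <- matrix(0, 1, 800); sp[1, seq(20, 780, by = 40)] <- 1
  tr <- sample_trace(sp, cp, seed = 1)
  est <- init_calcium_head(tr)
  expect_equal(est$alphas[1, 1], 0.9, tolerance = 1e-6)
  expect_equal(est$c[1], 1.2, tolerance = 0.011)

  # across a population: estimates correlate with the truth
  N <- 30
  al <- runif(N, 0.8, 0.95); cc <- runif(N, 0.8, 1.2)
  cpN <- calcium_params(alphas = al, c = cc, sigma2 = 1e-3)
  spN <- matrix(rpois(N * 2000, 0.3), N)
  trN <- sample_trace(spN, cpN, noise_sd_extra = 0.05, seed = 2)
  estN <- init_calcium_head(trN)
  expect_gt(cor(estN$alphas[, 1], al), 0.7)
  expect_gt(cor(estN$c, cc), 0.7)
})
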