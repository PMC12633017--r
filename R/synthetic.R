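#' Simulate a sequentially-firing population from a chain-structured HMM
#'
#' Generates the chain benchmark: K states with a cyclic transition matrix
#' (probability 5/6 of staying, 1/6 of advancing to the next state, last
#' state looping to the first), neurons split into K groups of equal size,
#' each group firing at `rate_active` spikes/bin in its state and
#' `rate_background` otherwise. Spikes are pushed through the AR(1) calcium
#' observation model (per-neuron decay drawn from a clipped normal) and
#' independent Gaussian measurement noise is added on top of the generated
#' traces — so the data are deliberately mismatched to every fitted model.
#' Two independent sequences (train and test) are produced.
#'
#' @param n_states Number of chain states K.
#' @param neurons_per_state Group size (total neurons = K x group size).
#' @param n_time Length of each generated sequence (bins).
#' @param rate_active Firing rate of a group in its own state (spikes/bin).
#' @param rate_background Firing rate elsewhere (spikes/bin); the default 0
#'   makes each neuron fire only in its group's state.
#' @param alpha_mean,alpha_sd,alpha_clip Decay coefficient distribution:
#'   normal with the given mean and standard deviation (default sd
#'   `sqrt(0.1)`, i.e. variance 0.1), clipped to `alpha_clip`, leaving an
#'   appreciable fraction of neurons at the bounds, including very slow
#'   decays at 0.95.
#' @param c Fluorescence influx per spike.
#' @param sigma2 AR process noise variance.
#' @param measurement_noise_sd Additive measurement noise (outside the AR
#'   recursion).
#' @param dt Bin width (seconds).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return A list with `train`/`test` (`trace_set`s), `train_states`,
#'   `test_states`, `train_spikes`, `test_spikes`, and `params` (true `pi0`,
#'   `P`, `rates` K x N, `obs_params`).
#' @examples
#' sim <- simulate_chain_hmm(n_time = 200, seed = 1)
#' sim$params$P[1, 1:2]   # 5/6 stay, 1/6 advance
#' @export
simulate_chain_hmm <- function(n_states = 5L, neurons_per_state = 5L,
                               n_time = 2000L, rate_active = 0.2,
                               rate_background = 0,
                               alpha_mean = 0.8, alpha_sd = sqrt(0.1),
                               alpha_clip = c(0.6, 0.95),
                               c = 1.0, sigma2 = 1e-2,
                               measurement_noise_sd = 0.2,
                               dt = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- as.integer(n_states)
  N <- K * as.integer(neurons_per_state)
  P <- matrix(0, K, K)
  for (k in seq_len(K)) {
    P[k, k] <- 5 / 6
    P[k, if (k == K) 1L else k + 1L] <- 1 / 6
  }
  pi0 <- rep(1 / K, K)
  rates <- matrix(rate_background, K, N)
  for (k in seq_len(K)) {
    grp <- ((k - 1L) * neurons_per_state + 1L):(k * neurons_per_state)
    rates[k, grp] <- rate_active
  }
  alphas <- pmin(pmax(stats::rnorm(N, alpha_mean, alpha_sd),
                      alpha_clip[1L]), alpha_clip[2L])
  obs <- calcium_params(alphas = alphas, c = c, sigma2 = sigma2)
  gen_seq <- function() {
    states <- integer(n_time)
    states[1L] <- sample.int(K, 1L, prob = pi0)
    for (t in seq_len(n_time - 1L))
      states[t + 1L] <- sample.int(K, 1L, prob = P[states[t], ])
    lam <- t(rates[states, , drop = FALSE])
    spikes <- matrix(stats::rpois(N * n_time, lam), N, n_time)
    y <- sample_trace(spikes, obs, noise_sd_extra = measurement_noise_sd,
                      dt = dt)
    list(states = states, spikes = spikes, y = y)
  }
  tr <- gen_seq(); te <- gen_seq()
  list(train = tr$y, test = te$y,
       train_states = tr$states, test_states = te$states,
       train_spikes = tr$spikes, test_spikes = te$spikes,
       params = list(pi0 = pi0, P = P, rates = rates, obs_params = obs),
       recipe = list(kind = "chain_hmm", n_states = K, n_neurons = N,
                     n_time = n_time, rate_active = rate_active,
                     rate_background = rate_background,
                     measurement_noise_sd = measurement_noise_sd,
                     dt = dt, seed = seed))
}

#' Simulate a population driven by smooth Gaussian-process latents
#'
#' Draws `length(lengthscales)` latent trajectories from squared-exponential
#' Gaussian processes, maps them to per-neuron Poisson rates through a linear
#' readout and a nonlinearity, samples spikes, and generates fluorescence via
#' the AR calcium observation model plus additive measurement noise. The
#' default AR(2) dynamics (a fast rise root and a slow decay root per neuron)
#' emulate the finite onset kinetics of real calcium indicators, which is
#' what gives a second-order observation model an edge over AR(1) on such
#' data.
#'
#' @param n_neurons Number of neurons.
#' @param n_time Number of bins.
#' @param lengthscales GP length-scales (bins), one per latent dimension.
#' @param ar_order 1 or 2 for the generative calcium dynamics.
#' @param nonlinearity `"softplus"` or `"exp"` rate nonlinearity.
#' @param mean_rate Approximate mean firing rate (spikes/bin) used to set the
#'   readout offsets.
#' @param loading_sd Standard deviation of the Gaussian loading entries.
#' @param measurement_noise_sd Additive measurement noise sd.
#' @param c_range,sigma2 Influx range (uniform per neuron) and process noise.
#' @param jitter Diagonal jitter for the GP Gram Cholesky.
#' @param dt Bin width (seconds).
#' @param seed RNG seed.
#' @return A list with `y` (`trace_set`), `latents` (p x T), `spikes`,
#'   `rates`, and `params` (loadings, offsets, lengthscales, `obs_params`).
#' @export
simulate_gp_latents <- function(n_neurons = 30L, n_time = 4000L,
                                lengthscales = c(250, 450, 500),
                                ar_order = 2L,
                                nonlinearity = c("softplus", "exp"),
                                mean_rate = 0.2, loading_sd = 0.6,
                                measurement_noise_sd = 0.2,
                                c_range = c(0.8, 1.2), sigma2 = 1e-2,
                                jitter = 1e-6, dt = 1, seed = NULL) {
  nonlinearity <- match.arg(nonlinearity)
  if (!is.null(seed)) set.seed(seed)
  p <- length(lengthscales)
  N <- as.integer(n_neurons); T <- as.integer(n_time)
  X <- matrix(0, p, T)
  for (j in seq_len(p)) {
    Kj <- rbf_gram(seq_len(T), lengthscales[j], jitter = jitter)
    X[j, ] <- drop(crossprod(chol(Kj), stats::rnorm(T)))
  }
  C <- matrix(stats::rnorm(N * p, sd = loading_sd), N, p)
  f <- if (nonlinearity == "softplus") function(e) log1p(exp(pmin(e, 30)))
       else function(e) exp(pmin(e, 30))
  d <- rep(if (nonlinearity == "softplus") log(expm1(mean_rate))
           else log(mean_rate), N)
  rates <- f(C %*% X + d)
  spikes <- matrix(stats::rpois(N * T, rates), N, T)
  if (ar_order == 2L) {
    decay <- stats::runif(N, 0.85, 0.95)
    rise <- stats::runif(N, 0.3, 0.6)
    alphas <- cbind(decay + rise, -decay * rise)
  } else {
    alphas <- matrix(stats::runif(N, 0.8, 0.95), ncol = 1L)
  }
  obs <- calcium_params(alphas = alphas,
                        c = stats::runif(N, c_range[1L], c_range[2L]),
                        sigma2 = sigma2)
  y <- sample_trace(spikes, obs, noise_sd_extra = measurement_noise_sd, dt = dt)
  list(y = y, latents = X, spikes = spikes, rates = rates,
       params = list(loadings = C, offsets = d, lengthscales = lengthscales,
                     nonlinearity = nonlinearity, obs_params = obs),
       recipe = list(kind = "gp_latents", n_neurons = N, n_time = T,
                     lengthscales = lengthscales, ar_order = ar_order,
                     mean_rate = mean_rate,
                     measurement_noise_sd = measurement_noise_sd, seed = seed))
}

#' Integrate the Lorenz system with fourth-order Runge-Kutta
#'
#' @param x0 Initial state (length 3).
#' @param n_steps Number of RK4 steps.
#' @param dt Step size.
#' @param sigma,rho,beta Lorenz coefficients (canonical chaotic regime by
#'   default).
#' @return Matrix 3 x (n_steps + 1) of states including the initial one.
#' @export
lorenz_rk4 <- function(x0, n_steps, dt = 0.025,
                       sigma = 10, rho = 28, beta = 8 / 3) {
  f <- function(s) c(sigma * (s[2L] - s[1L]),
                     s[1L] * (rho - s[3L]) - s[2L],
                     s[1L] * s[2L] - beta * s[3L])
  out <- matrix(0, 3L, n_steps + 1L)
  out[, 1L] <- x0
  s <- x0
  for (i in seq_len(n_steps)) {
    k1 <- f(s); k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2); k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[, i + 1L] <- s
  }
  out
}

#' Simulate trial-structured calcium data from Lorenz-attractor latents
#'
#' Integrates the Lorenz system (RK4, canonical coefficients) from random
#' initial conditions per trial with a burn-in to land on the attractor,
#' standardizes the three latent coordinates across the batch, maps them to
#' Poisson rates via an exponential-link linear readout whose offsets are
#' calibrated so the realized mean spike count per bin matches `mean_rate`,
#' samples spikes, and generates per-trial fluorescence via the AR(1)
#' calcium model plus measurement noise (which is outside the fitted
#' generative model).
#'
#' @param n_trials Number of trials.
#' @param trial_len Bins per trial.
#' @param n_neurons Number of neurons.
#' @param dt Lorenz integration step (also the recorded bin width).
#' @param mean_rate Target mean spikes/bin across the batch.
#' @param alpha_range,c_range Uniform sampling ranges for per-neuron decay
#'   and influx.
#' @param sigma2 AR process noise variance.
#' @param measurement_noise_sd Additive measurement noise sd.
#' @param burn_in RK4 steps discarded before recording each trial.
#' @param seed RNG seed.
#' @return A list with `y` (trial-structured `trace_set`), `latents`
#'   (3 x trials*len, standardized), `spikes`, `rates`, and `params`
#'   (loadings, offsets, `obs_params`).
#' @export
simulate_lorenz <- function(n_trials = 400L, trial_len = 100L,
                            n_neurons = 30L, dt = 0.025, mean_rate = 0.42,
                            alpha_range = c(0.8, 0.95),
                            c_range = c(0.8, 1.2), sigma2 = 1e-3,
                            measurement_noise_sd = 0.2, burn_in = 50L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(n_neurons)
  Ttot <- n_trials * trial_len
  lat <- matrix(0, 3L, Ttot)
  for (tr in seq_len(n_trials)) {
    x0 <- c(stats::rnorm(2L, 0, 5), stats::rnorm(1L, 25, 5))
    path <- lorenz_rk4(x0, burn_in + trial_len - 1L, dt = dt)
    lat[, ((tr - 1L) * trial_len + 1L):(tr * trial_len)] <-
      path[, (burn_in + 1L):(burn_in + trial_len)]
  }
  lat <- (lat - rowMeans(lat)) / apply(lat, 1L, stats::sd)
  W <- matrix(stats::rnorm(N * 3L), N, 3L)
  W <- W / sqrt(rowSums(W^2))
  eta <- W %*% lat
  d <- log(mean_rate) - log(rowMeans(exp(eta)))   # exact per-neuron calibration
  rates <- exp(eta + d)
  spikes <- matrix(stats::rpois(N * Ttot, rates), N, Ttot)
  obs <- calcium_params(
    alphas = matrix(stats::runif(N, alpha_range[1L], alpha_range[2L]), ncol = 1L),
    c = stats::runif(N, c_range[1L], c_range[2L]), sigma2 = sigma2)
  trial_ids <- rep(seq_len(n_trials), each = trial_len)
  y <- sample_trace(spikes, obs, noise_sd_extra = measurement_noise_sd,
                    dt = dt, trial_ids = trial_ids)
  list(y = y, latents = lat, spikes = spikes, rates = rates,
       params = list(loadings = W, offsets = d, obs_params = obs),
       recipe = list(kind = "lorenz", n_trials = n_trials,
                     trial_len = trial_len, n_neurons = N, dt = dt,
                     mean_rate = mean_rate,
                     measurement_noise_sd = measurement_noise_sd,
                     burn_in = burn_in, seed = seed))
}
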