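# Sequential variational autoencoder with nonlinear recurrent latent
# dynamics and a marginalized calcium observation head.
#
# Generative model per trial: x0 ~ N(0, sic2 I); u_t an AR(1) process;
# x_t = GRU(x_{t-1}, u_t); spike rates exp(C x_t + d); fluorescence via the
# Poisson-marginalized AR calcium likelihood (or Gaussian baseline).
# Inference: bidirectional GRU encoder -> q(x0); a forward GRU over the
# encoder's per-step outputs -> q(u_t). The controller is acausal but does
# not receive generator feedback, which keeps encoder and generator
# backpropagation decoupled.

# [B,N,T] array <-> N x (B*T) matrix (trial index fastest along columns)
to_big <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
}
from_big <- function(M, B, T) {
  aperm(array(M, c(nrow(M), B, T)), c(2L, 1L, 3L))
}

lfads_init_theta <- function(cfg, obs_init) {
  g <- cfg$g; He <- cfg$He; Hc <- cfg$Hc; U <- cfg$U; N <- cfg$N
  th <- list(enc_f = gru_params(N, He), enc_b = gru_params(N, He),
             ctrl = gru_params(2L * He, Hc), gen = gru_params(U, g))
  th$W_ic <- matrix(stats::rnorm(2L * He * 2L * g, sd = 1 / sqrt(2 * He)),
                    2L * He, 2L * g)
  th$b_ic <- c(rep(0, g), rep(-1, g))        # modest initial q(x0) variance
  th$W_u <- matrix(stats::rnorm(Hc * 2L * U, sd = 1 / sqrt(Hc)), Hc, 2L * U)
  th$b_u <- c(rep(0, U), rep(-1, U))
  th$C <- matrix(stats::rnorm(g * N, sd = 1 / sqrt(g)), g, N)
  if (cfg$obs == "calcium") {
    th$d <- rep(log(max(cfg$rate_guess, 1e-3)), N)
    th$alpha <- obs_init$alphas[, 1L]
    th$logc <- log(obs_init$c)
    th$logs2 <- log(obs_init$sigma2)
  } else {
    th$d <- rep(0, N)
    th$logpsi <- rep(log(0.5), N)
  }
  th
}

# One ELBO evaluation (and optionally gradients) on a batch Y [B,N,T].
lfads_step <- function(th, Y, cfg, kl_weight = 1, want_grads = TRUE) {
  B <- dim(Y)[1L]; N <- dim(Y)[2L]; T <- dim(Y)[3L]
  g <- cfg$g; He <- cfg$He; Hc <- cfg$Hc; U <- cfg$U
  i1 <- seq_len(He)
  # ---- encoder ----
  h0e <- matrix(0, B, He)
  ef <- gru_forward(th$enc_f, Y, h0e)
  eb <- gru_forward(th$enc_b, Y[, , T:1, drop = FALSE], h0e)
  E <- array(0, c(B, 2L * He, T))
  E[, i1, ] <- ef$h
  E[, He + i1, ] <- eb$h[, , T:1, drop = FALSE]
  e_ic <- cbind(matrix(ef$h[, , T], B), matrix(eb$h[, , T], B))
  icv <- e_ic %*% th$W_ic + rep(th$b_ic, each = B)
  mu0 <- icv[, seq_len(g), drop = FALSE]
  logv0 <- pmin(icv[, g + seq_len(g), drop = FALSE], 8)
  # ---- controller ----
  cf <- gru_forward(th$ctrl, E, matrix(0, B, Hc))
  mu_u <- array(0, c(B, U, T)); logv_u <- array(0, c(B, U, T))
  for (t in seq_len(T)) {
    uv <- matrix(cf$h[, , t], B) %*% th$W_u + rep(th$b_u, each = B)
    mu_u[, , t] <- uv[, seq_len(U)]
    logv_u[, , t] <- pmin(uv[, U + seq_len(U)], 8)
  }
  # ---- sample ----
  sd0 <- exp(logv0 / 2)
  eps0 <- matrix(stats::rnorm(B * g), B, g)
  x0 <- mu0 + sd0 * eps0
  sdu <- exp(logv_u / 2)
  eps_u <- array(stats::rnorm(B * U * T), c(B, U, T))
  u <- mu_u + sdu * eps_u
  # ---- generator + readout ----
  gf <- gru_forward(th$gen, u, x0)
  hg_flat <- matrix(aperm(gf$h, c(1L, 3L, 2L)), B * T, g)
  eta_all <- hg_flat %*% th$C + rep(th$d, each = B * T)   # (B*T) x N
  # ---- likelihood ----
  if (cfg$obs == "calcium") {
    alpha <- th$alpha; cvec <- exp(th$logc); s2 <- exp(th$logs2)
    Ylag <- array(0, dim(Y))
    Ylag[, , 2:T] <- Y[, , 1:(T - 1L)]
    delta_big <- to_big(Y - Ylag * rep(alpha, each = B))
    rates_big <- exp(pmin(pmax(t(eta_all), -50), 20))
    out <- .calcium_marglik_cpp(delta_big, rates_big, cvec, s2,
                                as.integer(cfg$max_count), TRUE)
    ll <- sum(out$ll)
  } else {
    psi <- exp(th$logpsi)
    resid_big <- to_big(Y) - t(eta_all)
    ll <- sum(stats::dnorm(resid_big, 0, sqrt(psi), log = TRUE))
  }
  # ---- KL terms ----
  v0 <- exp(logv0)
  kl0 <- 0.5 * sum((v0 + mu0^2) / cfg$sic2 - 1 - logv0 + log(cfg$sic2))
  a <- cfg$a; bu <- cfg$b; su2 <- cfg$su2
  V1 <- su2 / (1 - a^2); m1 <- bu / (1 - a)
  vu <- exp(logv_u)
  klu <- 0
  dmu_u <- if (want_grads) array(0, dim(mu_u)) else NULL
  dv_u <- if (want_grads) array(0, dim(mu_u)) else NULL
  for (t in seq_len(T)) {
    mt <- mu_u[, , t, drop = FALSE]; vt <- vu[, , t, drop = FALSE]
    if (t == 1L) {
      klu <- klu + sum(0.5 * (log(V1) - logv_u[, , t]) +
                         ((mt - m1)^2 + vt) / (2 * V1) - 0.5)
      if (want_grads) {
        dmu_u[, , t] <- dmu_u[, , t] + (mt - m1) / V1
        dv_u[, , t] <- dv_u[, , t] + 1 / (2 * V1) - 1 / (2 * vt)
      }
    } else {
      mp <- mu_u[, , t - 1L, drop = FALSE]; vp <- vu[, , t - 1L, drop = FALSE]
      r <- mt - a * mp - bu
      klu <- klu + sum(0.5 * (log(su2) - logv_u[, , t]) +
                         (r^2 + vt + a^2 * vp) / (2 * su2) - 0.5)
      if (want_grads) {
        dmu_u[, , t] <- dmu_u[, , t] + r / su2
        dmu_u[, , t - 1L] <- dmu_u[, , t - 1L] - a * r / su2
        dv_u[, , t] <- dv_u[, , t] + 1 / (2 * su2) - 1 / (2 * vt)
        dv_u[, , t - 1L] <- dv_u[, , t - 1L] + a^2 / (2 * su2)
      }
    }
  }
  kl <- kl0 + klu
  obj <- (ll - kl_weight * kl) / B
  res <- list(obj = obj, ll = ll / B, kl = kl / B, elbo = (ll - kl) / B)
  if (!want_grads) return(res)
  # ================= backward =================
  sc <- 1 / B
  if (cfg$obs == "calcium") {
    deta_big <- out$en - rates_big                  # N x (B*T)
    ddelta <- -(delta_big - cvec * out$en) / s2
    ylag_big <- to_big(Ylag)
    dalpha <- -rowSums(ddelta * ylag_big) * sc
    dlogc <- (rowSums(delta_big * out$en - cvec * out$en2) / s2) * cvec * sc
    e2 <- delta_big^2 - 2 * cvec * delta_big * out$en + cvec^2 * out$en2
    dlogs2 <- (rowSums(e2 - s2) / (2 * s2^2)) * s2 * sc
  } else {
    deta_big <- resid_big / psi
    dlogpsi <- rowSums((resid_big^2 - psi) / (2 * psi)) * sc
  }
  deta_all <- t(deta_big) * sc                      # (B*T) x N
  gC <- crossprod(hg_flat, deta_all)
  gd <- colSums(deta_all)
  dhg_flat <- deta_all %*% t(th$C)
  dh_seq_gen <- aperm(array(dhg_flat, c(B, T, g)), c(1L, 3L, 2L))
  gb <- gru_backward(th$gen, gf$cache, dh_seq_gen)
  du <- gb$dX                                        # B x U x T
  dx0 <- gb$dh0                                      # B x g
  w <- kl_weight * sc
  # q(x0) heads
  dmu0 <- dx0 - w * (mu0 / cfg$sic2)
  dlogv0 <- dx0 * eps0 * 0.5 * sd0 - w * 0.5 * (v0 / cfg$sic2 - 1)
  dicv <- cbind(dmu0, dlogv0)
  gW_ic <- crossprod(e_ic, dicv)
  gb_ic <- colSums(dicv)
  de_ic <- dicv %*% t(th$W_ic)
  # q(u) heads
  dmu_all <- du - w * dmu_u
  dlogv_all <- du * eps_u * 0.5 * sdu - w * dv_u * vu
  gW_u <- th$W_u * 0; gb_u <- th$b_u * 0
  dh_seq_ctrl <- array(0, c(B, Hc, T))
  for (t in seq_len(T)) {
    duv <- cbind(matrix(dmu_all[, , t], B), matrix(dlogv_all[, , t], B))
    hct <- matrix(cf$h[, , t], B)
    gW_u <- gW_u + crossprod(hct, duv)
    gb_u <- gb_u + colSums(duv)
    dh_seq_ctrl[, , t] <- duv %*% t(th$W_u)
  }
  cb <- gru_backward(th$ctrl, cf$cache, dh_seq_ctrl)
  dE <- cb$dX                                        # B x 2He x T
  fb_ <- gru_backward(th$enc_f, ef$cache, dE[, i1, , drop = FALSE],
                      dh_last = de_ic[, i1, drop = FALSE])
  dh_seq_b <- dE[, He + i1, T:1, drop = FALSE]
  bb <- gru_backward(th$enc_b, eb$cache, dh_seq_b,
                     dh_last = de_ic[, He + i1, drop = FALSE])
  grads <- list(enc_f = fb_$grads, enc_b = bb$grads, ctrl = cb$grads,
                gen = gb$grads, W_ic = gW_ic, b_ic = gb_ic,
                W_u = gW_u, b_u = gb_u, C = gC, d = gd)
  if (cfg$obs == "calcium") {
    grads$alpha <- dalpha; grads$logc <- dlogc; grads$logs2 <- dlogs2
  } else grads$logpsi <- dlogpsi
  res$grads <- grads
  res
}

# Convert a trial-structured trace_set to a [trials, neurons, time] array.
trials_array <- function(y) {
  y <- as_trace_set(y)
  mats <- trial_split(y)
  Tlen <- unique(vapply(mats, ncol, integer(1)))
  if (length(Tlen) != 1L) stop("trials must have equal lengths")
  B <- length(mats)
  out <- array(0, c(B, nrow(mats[[1L]]), Tlen))
  for (b in seq_len(B)) out[b, , ] <- mats[[b]]
  out
}

#' Initialize the calcium observation head from data
#'
#' Per-neuron heuristic estimates of the AR decay and influx used to
#' initialize the observation head before variational training: the decay is
#' a lag regression restricted to decreasing segments of the trace, and the
#' influx is a grid sweep over 0.8-2.2 aligning the positive one-step
#' increments with quantized jump sizes (see [init_neuron_params()]).
#'
#' @param y A trial-structured `trace_set` (trials are concatenated for the
#'   per-neuron regressions).
#' @return A [calcium_params()] object (AR order 1).
#' @export
init_calcium_head <- function(y) {
  init_neuron_params(as_trace_set(y), ar_order = 1L,
                     c_grid = seq(0.8, 2.2, by = 0.01), decay_only = TRUE)
}

#' Fit a sequential variational autoencoder with calcium observations
#'
#' Fits nonlinear latent dynamics to trial-structured fluorescence data. Per
#' trial, a latent initial state and a sequence of low-dimensional inferred
#' inputs (with an AR(1) prior) drive a GRU generator; generator states map
#' to Poisson spike rates through an exponential linear readout; observed
#' traces follow the spike-marginalized AR(1) calcium likelihood
#' (`obs = "calcium"`) or a Gaussian likelihood on the readout
#' (`obs = "gaussian"`). Amortized inference uses a bidirectional GRU
#' encoder for the initial state and a forward GRU controller for the
#' inputs; the evidence lower bound is maximized by Adam with a linear KL
#' warmup. The calcium head (per-neuron decay, influx, noise) is initialized
#' from the data by [init_calcium_head()] and refined during training.
#'
#' @param y Trial-structured `trace_set` with equal-length trials.
#' @param gen_dim Generator (latent dynamics) state size.
#' @param encoder_dim,controller_dim Encoder and controller GRU sizes.
#' @param u_dim Dimension of the inferred inputs.
#' @param obs Observation model.
#' @param epochs Training epochs.
#' @param batch_size Trials per gradient step.
#' @param lr Adam step size (decayed linearly to a tenth).
#' @param kl_warmup Steps over which the KL weight ramps 0 to 1.
#' @param ic_prior_var Prior variance of the initial state.
#' @param input_prior List `(a, b, var)` of the AR(1) prior on inputs.
#' @param max_count Spike-count truncation of the calcium likelihood.
#' @param alpha_clip Clip range for the AR decay during training.
#' @param obs_init Optional [calcium_params()] overriding the data-driven
#'   initialization of the observation head.
#' @param seed RNG seed.
#' @param verbose Print progress every 20 steps.
#' @return An object of class `calcium_lfads` with the trained parameter
#'   list `theta`, `config`, `elbo_trace` (per step, unit KL weight),
#'   `obs_params` (for the calcium head) and the training `y`.
#' @export
calcium_lfads <- function(y, gen_dim = 32L, encoder_dim = 64L,
                          controller_dim = 32L, u_dim = 1L,
                          obs = c("calcium", "gaussian"),
                          epochs = 50L, batch_size = 40L, lr = 1e-3,
                          kl_warmup = 500L, ic_prior_var = 1,
                          input_prior = list(a = 0.9, b = 0, var = 0.1),
                          max_count = 10L, alpha_clip = c(0.5, 0.98),
                          obs_init = NULL, seed = NULL, verbose = FALSE) {
  obs <- match.arg(obs)
  y <- as_trace_set(y)
  if (!is.null(seed)) set.seed(seed)
  Y <- trials_array(y)
  B_all <- dim(Y)[1L]; N <- dim(Y)[2L]; T <- dim(Y)[3L]
  cfg <- list(N = N, T = T, g = as.integer(gen_dim), He = as.integer(encoder_dim),
              Hc = as.integer(controller_dim), U = as.integer(u_dim), obs = obs,
              sic2 = ic_prior_var, a = input_prior$a, b = input_prior$b,
              su2 = input_prior$var, max_count = as.integer(max_count),
              rate_guess = max(mean(pmax(Y, 0)), 1e-3))
  if (obs == "calcium" && is.null(obs_init))
    obs_init <- suppressWarnings(init_calcium_head(y))
  th <- lfads_init_theta(cfg, obs_init)
  opt <- adam_new(flatten_params(th))
  n_batches <- max(1L, floor(B_all / batch_size))
  total_steps <- epochs * n_batches
  elbo_trace <- numeric(0)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(B_all)
    for (bi in seq_len(n_batches)) {
      step <- step + 1L
      sel <- ord[((bi - 1L) * batch_size + 1L):
                   min(bi * batch_size, B_all)]
      w <- min(1, step / max(kl_warmup, 1L))
      st <- lfads_step(th, Y[sel, , , drop = FALSE], cfg, kl_weight = w)
      if (!is.finite(st$obj))
        stop("training loss became non-finite at step ", step,
             "; aborting (lower the learning rate)")
      elbo_trace <- c(elbo_trace, st$elbo)
      lr_t <- lr * (1 - 0.9 * (step - 1) / total_steps)
      flat <- adam_step(opt, flatten_params(th), flatten_params(st$grads),
                        lr_t, maximize = TRUE, clip = 200)
      th <- unflatten_params(flat)
      if (obs == "calcium")
        th$alpha <- pmin(pmax(th$alpha, alpha_clip[1L]), alpha_clip[2L])
      if (verbose && step %% 20L == 0L)
        message(sprintf("  epoch %3d step %5d  ELBO/trial %.2f (KL w %.2f)",
                        ep, step, st$elbo, w))
    }
  }
  obs_params <- if (obs == "calcium")
    calcium_params(matrix(th$alpha, ncol = 1L), c = exp(th$logc),
                   sigma2 = exp(th$logs2)) else NULL
  out <- list(theta = th, config = cfg, elbo_trace = elbo_trace,
              obs = obs, obs_params = obs_params, y = y, call = match.call())
  class(out) <- "calcium_lfads"
  out
}

#' @export
print.calcium_lfads <- function(x, ...) {
  cat(sprintf(
    "<calcium_lfads> generator %d, inputs %d, obs = '%s'\n  final ELBO/trial %.2f after %d steps\n",
    x$config$g, x$config$U, x$obs,
    mean(utils::tail(x$elbo_trace, 10)), length(x$elbo_trace)))
  invisible(x)
}

#' @export
logLik.calcium_lfads <- function(object, ...) {
  structure(mean(utils::tail(object$elbo_trace, 10)), df = NA_integer_,
            class = "logLik")
}

# Deterministic amortized-posterior pass: encoder/controller means, no noise.
lfads_infer <- function(object, Y) {
  th <- object$theta; cfg <- object$config
  B <- dim(Y)[1L]; T <- dim(Y)[3L]
  He <- cfg$He; g <- cfg$g; U <- cfg$U
  i1 <- seq_len(He)
  ef <- gru_forward(th$enc_f, Y, matrix(0, B, He))
  eb <- gru_forward(th$enc_b, Y[, , T:1, drop = FALSE], matrix(0, B, He))
  E <- array(0, c(B, 2L * He, T))
  E[, i1, ] <- ef$h
  E[, He + i1, ] <- eb$h[, , T:1, drop = FALSE]
  e_ic <- cbind(matrix(ef$h[, , T], B), matrix(eb$h[, , T], B))
  icv <- e_ic %*% th$W_ic + rep(th$b_ic, each = B)
  x0 <- icv[, seq_len(g), drop = FALSE]
  cf <- gru_forward(th$ctrl, E, matrix(0, B, cfg$Hc))
  u <- array(0, c(B, U, T))
  for (t in seq_len(T)) {
    uv <- matrix(cf$h[, , t], B) %*% th$W_u + rep(th$b_u, each = B)
    u[, , t] <- uv[, seq_len(U)]
  }
  gf <- gru_forward(th$gen, u, x0)
  hg_flat <- matrix(aperm(gf$h, c(1L, 3L, 2L)), B * T, g)
  eta_all <- hg_flat %*% th$C + rep(th$d, each = B * T)
  rates <- from_big(exp(pmin(t(eta_all), 20)), B, T)
  list(factors = gf$h, rates = rates, u = u, x0 = x0)
}

#' Posterior factors, rates or inputs from a fitted model
#'
#' Runs the deterministic amortized inference pass (posterior means) on the
#' training data or on new trials and returns the requested quantity.
#'
#' @param object A fitted `calcium_lfads`.
#' @param newdata Optional `trace_set` (equal trial length as training).
#' @param type `"factors"` (generator states, trials x gen_dim x time),
#'   `"rates"` (trials x neurons x time), `"u"` (inferred inputs), or
#'   `"x0"` (initial-state means).
#' @param ... Unused.
#' @export
predict.calcium_lfads <- function(object, newdata = NULL,
                                  type = c("factors", "rates", "u", "x0"),
                                  ...) {
  type <- match.arg(type)
  Y <- trials_array(if (is.null(newdata)) object$y else as_trace_set(newdata))
  lfads_infer(object, Y)[[type]]
}

#' Monte Carlo ELBO of a fitted sequential VAE
#'
#' @param object A fitted `calcium_lfads`.
#' @param newdata Optional `trace_set`; default is the training data.
#' @param kl_weight Weight on the KL term (1 = the proper bound).
#' @param seed RNG seed for the reparameterized sample.
#' @return List with `elbo` (per trial, unit KL), `objective` (with the
#'   requested weight), `ll`, `kl`.
#' @export
lfads_elbo <- function(object, newdata = NULL, kl_weight = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- trials_array(if (is.null(newdata)) object$y else as_trace_set(newdata))
  st <- lfads_step(object$theta, Y, object$config, kl_weight = kl_weight,
                   want_grads = FALSE)
  list(elbo = st$elbo, objective = st$obj, ll = st$ll, kl = st$kl)
}

#' Roll out the generative model
#'
#' Deterministic GRU rollout from given initial states and input sequences,
#' followed by sampled Poisson spikes and sampled fluorescence traces.
#'
#' @param object A fitted `calcium_lfads` (calcium observation model).
#' @param x0 Matrix trials x gen_dim of initial states.
#' @param u Array trials x u_dim x time of inputs.
#' @param seed RNG seed for the spike/trace sampling.
#' @return List with `factors`, `rates`, `spikes`, `traces` (all
#'   trial-major arrays; `traces` a `trace_set`).
#' @export
lfads_rollout <- function(object, x0, u, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- object$theta; cfg <- object$config
  B <- nrow(x0); T <- dim(u)[3L]
  gf <- gru_forward(th$gen, u, x0)
  hg_flat <- matrix(aperm(gf$h, c(1L, 3L, 2L)), B * T, cfg$g)
  eta_all <- hg_flat %*% th$C + rep(th$d, each = B * T)
  rates_big <- exp(pmin(t(eta_all), 20))
  spikes_big <- matrix(stats::rpois(length(rates_big), rates_big),
                       nrow(rates_big))
  out <- list(factors = gf$h, rates = from_big(rates_big, B, T),
              spikes = from_big(spikes_big, B, T))
  if (cfg$obs == "calcium") {
    op <- calcium_params(matrix(th$alpha, ncol = 1L), c = exp(th$logc),
                         sigma2 = exp(th$logs2))
    trial_ids <- rep(seq_len(B), each = T)
    sp_flat <- matrix(aperm(out$spikes, c(2L, 3L, 1L)), cfg$N, B * T)
    out$traces <- sample_trace(sp_flat, op, dt = object$y$dt,
                               trial_ids = trial_ids)
  }
  out
}

#' Simulate trials from the fitted generative model
#'
#' Samples initial states from their prior, inputs from the AR(1) prior,
#' rolls out the generator and samples spikes and traces.
#'
#' @param object A fitted `calcium_lfads`.
#' @param nsim Number of trials.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return As [lfads_rollout()].
#' @export
simulate.calcium_lfads <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- object$config
  T <- cfg$T
  x0 <- matrix(stats::rnorm(nsim * cfg$g, sd = sqrt(cfg$sic2)), nsim, cfg$g)
  u <- array(0, c(nsim, cfg$U, T))
  V1 <- cfg$su2 / (1 - cfg$a^2)
  u[, , 1L] <- stats::rnorm(nsim * cfg$U, cfg$b / (1 - cfg$a), sqrt(V1))
  for (t in 2:T)
    u[, , t] <- cfg$a * u[, , t - 1L] + cfg$b +
      stats::rnorm(nsim * cfg$U, sd = sqrt(cfg$su2))
  lfads_rollout(object, x0, u)
}
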