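#' Squared-exponential Gram matrix
#'
#' Builds the T x T covariance `exp(-(t - t')^2 / (2 l^2))` of a
#' squared-exponential (RBF) Gaussian process on the given time grid, with a
#' diagonal jitter for numerical positive-definiteness. If the Cholesky
#' factorization fails the jitter is escalated (up to 1000x) before raising
#' an error with a condition-number estimate.
#'
#' @param times Numeric vector of time points (bins).
#' @param lengthscale Positive length-scale in the same units as `times`.
#' @param jitter Initial diagonal jitter.
#' @return The Gram matrix with attribute `"jitter"` (the value actually
#'   used).
#' @examples
#' K <- rbf_gram(1:5, lengthscale = 2)
#' K[1, 2]  # exp(-1/8)
#' @export
rbf_gram <- function(times, lengthscale, jitter = 1e-5) {
  if (lengthscale <= 0) stop("lengthscale must be > 0")
  D <- outer(times, times, "-")
  K <- exp(-D^2 / (2 * lengthscale^2))
  j <- jitter
  for (try in 1:4) {
    Kj <- K + j * diag(length(times))
    ok <- tryCatch({ chol(Kj); TRUE }, error = function(e) FALSE)
    if (ok) {
      attr(Kj, "jitter") <- j
      return(Kj)
    }
    j <- j * 10
  }
  stop(sprintf(
    "RBF Gram not positive definite after jitter escalation (kappa ~ %.3g)",
    kappa(K, exact = FALSE)))
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-pmin(abs(x), 50)))
sigmoid <- function(x) 1 / (1 + exp(-x))

# Rate nonlinearity and its derivative.
rate_fun <- function(nonlinearity) {
  if (nonlinearity == "softplus")
    list(f = function(e) softplus(e), df = function(e, r) sigmoid(e))
  else
    list(f = function(e) exp(pmin(e, 30)), df = function(e, r) r)
}

# Per-latent GP prior pieces shared across trials of equal length.
gp_prior_struct <- function(Tlen, lengthscales, jitter = 1e-5) {
  lapply(lengthscales, function(l) {
    K <- rbf_gram(seq_len(Tlen), l, jitter = jitter)
    R <- chol(K)
    Kinv <- chol2inv(R)
    list(Kinv = Kinv, diagKinv = diag(Kinv),
         logdet = 2 * sum(log(diag(R))))
  })
}

# KL(q || GP prior) and gradients for one latent dim on one trial.
# q = N(m, diag(v)); prior = N(0, K).
gp_kl <- function(m, v, prior) {
  Km <- drop(prior$Kinv %*% m)
  kl <- 0.5 * (sum(m * Km) + sum(prior$diagKinv * v) - length(m) +
                 prior$logdet - sum(log(v)))
  list(kl = kl, dm = Km, dv = 0.5 * (prior$diagKinv - 1 / v))
}

#' Gaussian process factor analysis for calcium traces
#'
#' Fits a GPFA model in which each latent dimension follows a
#' squared-exponential Gaussian process over time, latents map to per-neuron
#' Poisson rates through a linear readout and a nonlinearity, and the
#' observations are fluorescence traces under the spike-marginalized AR
#' calcium likelihood (`obs = "calcium"`, AR order 1 or 2). Baselines:
#' `obs = "gaussian"` models the traces directly as Gaussian around the
#' linear readout; `obs = "poisson"` fits Poisson-observation GPFA to spike
#' counts (e.g. externally deconvolved estimates) passed as the data matrix.
#'
#' Inference is black-box stochastic variational inference: the posterior
#' over latents is a diagonal (mean-field) Gaussian per time bin, the
#' expected log-likelihood is estimated with reparameterized Monte Carlo
#' samples, the KL to the GP prior is computed in closed form, and all
#' parameters (loadings, offsets, observation parameters, variational means
#' and scales) are updated by Adam. GP length-scales are fixed at their
#' initial values; the affine alignment used for evaluation absorbs residual
#' smoothness mismatch.
#'
#' @param y A `trace_set` or neurons-by-time matrix (counts when
#'   `obs = "poisson"`). Trials, if present, must have equal lengths.
#' @param n_latents Number of latent dimensions p.
#' @param obs Observation model.
#' @param ar_order AR order (1 or 2) of the calcium likelihood.
#' @param lengthscale GP length-scale(s) in bins (recycled over latents).
#' @param n_iter Number of stochastic gradient steps.
#' @param n_mc Monte Carlo samples per step.
#' @param lr Adam step size (decayed linearly to a tenth over training).
#' @param max_count Spike-count truncation for the calcium likelihood.
#' @param nonlinearity Rate nonlinearity, `"softplus"` or `"exp"`.
#' @param alpha_init Initial AR coefficients (default 0.51 for AR(1),
#'   `c(1.81, -0.81)` for AR(2), for every neuron).
#' @param seed RNG seed for the Monte Carlo stream.
#' @param verbose Print progress every 200 steps.
#' @return An object of class `calcium_gpfa` with loadings `C`, offsets `d`,
#'   `obs_params` (or `psi`), variational `means`/`scales` (p x T), and
#'   `elbo_trace`.
#' @examples
#' sim <- simulate_gp_latents(n_neurons = 8, n_time = 200,
#'                            lengthscales = c(30, 50), seed = 1)
#' fit <- calcium_gpfa(sim$y, n_latents = 2, ar_order = 2, lengthscale = 40,
#'                     n_iter = 200, seed = 1)
#' align_latents(sim$latents, predict(fit))$mean_r2
#' @export
calcium_gpfa <- function(y, n_latents,
                         obs = c("calcium", "gaussian", "poisson"),
                         ar_order = 1L, lengthscale = 350,
                         n_iter = 2000L, n_mc = 5L, lr = 1e-2,
                         max_count = 10L,
                         nonlinearity = c("softplus", "exp"),
                         alpha_init = NULL, seed = NULL, verbose = FALSE) {
  obs <- match.arg(obs)
  nonlinearity <- match.arg(nonlinearity)
  y <- as_trace_set(y)
  if (!is.null(seed)) set.seed(seed)
  vals <- y$values
  N <- nrow(vals); T <- ncol(vals); p <- as.integer(n_latents)
  trials <- if (is.null(y$trial_ids)) list(seq_len(T))
            else split(seq_len(T), y$trial_ids)
  Tlen <- unique(lengths(trials))
  if (length(Tlen) != 1L) stop("GPFA requires equal-length trials")
  ls <- rep_len(lengthscale, p)
  prior <- gp_prior_struct(Tlen, ls)
  nl <- rate_fun(nonlinearity)

  # --- initialization ---
  sv <- La.svd(vals - rowMeans(vals), nu = p, nv = 0)
  C <- sv$u * 0.1
  if (obs == "gaussian") {
    C <- sv$u %*% diag(sv$d[seq_len(p)] / sqrt(T), p)
    d <- rowMeans(vals)
    psi <- pmax(apply(vals, 1L, stats::var) * 0.5, 1e-4)
    obs_params <- NULL
  } else {
    base_rate <- max(mean(pmax(vals, 0)), 0.05)
    d <- rep(if (nonlinearity == "softplus") log(expm1(base_rate))
             else log(base_rate), N)
    psi <- NULL
    obs_params <- NULL
  }
  if (obs == "calcium") {
    if (is.null(alpha_init))
      alpha_init <- if (ar_order == 1L) 0.51 else c(1.81, -0.81)
    alphas <- matrix(rep(alpha_init, each = N), N, ar_order)
    s2 <- pmax(apply(vals, 1L, function(v) stats::var(diff(v))), 1e-4)
    obs_params <- calcium_params(alphas = alphas, c = rep(1, N), sigma2 = s2)
  }
  if (obs == "poisson" && any(vals < 0))
    stop("obs = 'poisson' expects nonnegative counts as data")
  if (obs == "poisson" && all(vals == 0))
    warning("all-zero spike counts: rates will degenerate toward zero")
  m <- matrix(0, p, T)
  logs <- matrix(log(0.7), p, T)
  # unconstrained observation parameterization
  th <- list(C = C, d = d, m = m, logs = logs)
  if (obs == "calcium") {
    th$alphas <- obs_params$alphas
    th$logc <- log(obs_params$c)
    th$logs2 <- log(obs_params$sigma2)
  } else if (obs == "gaussian") th$logpsi <- log(psi)

  opt <- adam_new(th)
  elbo_trace <- numeric(n_iter)
  lags <- if (obs == "calcium") lag_stack(vals, ar_order, y$trial_ids) else NULL
  lfac <- if (obs == "poisson") lgamma(vals + 1) else NULL

  for (it in seq_len(n_iter)) {
    g <- lapply(th, function(x) x * 0)
    # ---- KL term (closed form) ----
    v <- exp(2 * th$logs)
    kl <- 0
    for (j in seq_len(p)) for (ix in trials) {
      kj <- gp_kl(th$m[j, ix], v[j, ix], prior[[j]])
      kl <- kl + kj$kl
      g$m[j, ix] <- g$m[j, ix] - kj$dm
      g$logs[j, ix] <- g$logs[j, ix] - kj$dv * 2 * v[j, ix]
    }
    # ---- expected log-likelihood (MC, reparameterized) ----
    ell <- 0
    if (obs == "calcium") {
      cvec <- exp(th$logc); s2 <- exp(th$logs2)
      delta <- vals
      for (jj in seq_len(ar_order)) delta <- delta - th$alphas[, jj] * lags[[jj]]
    }
    svec <- exp(th$logs)
    for (s in seq_len(n_mc)) {
      eps <- matrix(stats::rnorm(p * T), p, T)
      x <- th$m + svec * eps
      eta <- th$C %*% x + th$d
      if (obs == "gaussian") {
        psi_ <- exp(th$logpsi)
        r <- vals - eta
        ell <- ell + sum(-0.5 * (log(2 * pi * psi_) + r^2 / psi_)) / n_mc
        deta <- (r / psi_) / n_mc
        g$logpsi <- g$logpsi + rowSums((r^2 - psi_) / (2 * psi_)) / n_mc
      } else if (obs == "poisson") {
        rate <- nl$f(eta) + 1e-10
        ell <- ell + sum(vals * log(rate) - rate - lfac) / n_mc
        deta <- ((vals / rate - 1) * nl$df(eta, rate)) / n_mc
      } else {
        rate <- nl$f(eta) + 1e-10
        out <- .calcium_marglik_cpp(delta, rate, cvec, s2,
                                    as.integer(max_count), TRUE)
        ell <- ell + sum(out$ll) / n_mc
        dlam <- out$en / rate - 1
        deta <- (dlam * nl$df(eta, rate)) / n_mc
        ddelta <- -(delta - cvec * out$en) / s2
        for (jj in seq_len(ar_order))
          g$alphas[, jj] <- g$alphas[, jj] -
            rowSums(ddelta * lags[[jj]]) / n_mc
        g$logc <- g$logc +
          (rowSums(delta * out$en - cvec * out$en2) / s2) * cvec / n_mc
        e2 <- delta^2 - 2 * cvec * delta * out$en + cvec^2 * out$en2
        g$logs2 <- g$logs2 +
          (rowSums(e2 - s2) / (2 * s2^2)) * s2 / n_mc
      }
      g$C <- g$C + deta %*% t(x)
      g$d <- g$d + rowSums(deta)
      dx <- crossprod(th$C, deta)
      g$m <- g$m + dx
      g$logs <- g$logs + dx * eps * svec
    }
    elbo_trace[it] <- ell - kl
    if (!is.finite(elbo_trace[it]))
      stop("ELBO diverged (non-finite) at iteration ", it)
    lr_t <- lr * (1 - 0.9 * (it - 1) / n_iter)
    th <- adam_step(opt, th, g, lr_t, maximize = TRUE)
    # floors keep variances away from collapse (and the arithmetic away
    # from subnormals)
    th$logs <- pmax(th$logs, log(1e-4))
    if (!is.null(th$logpsi)) th$logpsi <- pmax(th$logpsi, log(1e-4))
    if (!is.null(th$logs2)) th$logs2 <- pmax(th$logs2, log(1e-6))
    if (verbose && it %% 200L == 0L)
      message(sprintf("  VI iter %5d  ELBO %.2f", it, elbo_trace[it]))
  }
  obs_params_out <- if (obs == "calcium")
    calcium_params(th$alphas, c = exp(th$logc), sigma2 = exp(th$logs2))
  else NULL
  out <- list(C = th$C, d = th$d, obs = obs, obs_params = obs_params_out,
              psi = if (obs == "gaussian") exp(th$logpsi) else NULL,
              means = th$m, scales = exp(th$logs),
              lengthscales = ls, nonlinearity = nonlinearity,
              ar_order = if (obs == "calcium") ar_order else NA_integer_,
              elbo_trace = elbo_trace, n_mc = n_mc,
              max_count = max_count, y = y, call = match.call())
  class(out) <- "calcium_gpfa"
  out
}

#' @export
print.calcium_gpfa <- function(x, ...) {
  tail_elbo <- mean(utils::tail(x$elbo_trace, 50))
  cat(sprintf(
    "<calcium_gpfa> %d latents, %d neurons, obs = '%s'%s\n  ELBO (last-50 mean) %.2f after %d steps\n",
    nrow(x$means), nrow(x$C), x$obs,
    if (x$obs == "calcium") sprintf(" AR(%d)", x$ar_order) else "",
    tail_elbo, length(x$elbo_trace)))
  invisible(x)
}

#' @export
logLik.calcium_gpfa <- function(object, ...) {
  structure(mean(utils::tail(object$elbo_trace, 50)),
            df = NA_integer_, class = "logLik")
}

#' Posterior latent means or fitted rates from a GPFA fit
#'
#' @param object A fitted `calcium_gpfa`.
#' @param type `"latents"` (posterior means, p x T) or `"rates"` (rates at
#'   the posterior mean).
#' @param ... Unused.
#' @export
predict.calcium_gpfa <- function(object, type = c("latents", "rates"), ...) {
  type <- match.arg(type)
  if (type == "latents") return(object$means)
  eta <- object$C %*% object$means + object$d
  if (object$obs == "gaussian") eta else rate_fun(object$nonlinearity)$f(eta)
}

#' @export
plot.calcium_gpfa <- function(x, ...) {
  graphics::matplot(t(x$means), type = "l", lty = 1,
                    xlab = "time bin", ylab = "latent posterior mean", ...)
  invisible(x)
}

#' Monte Carlo ELBO of a fitted GPFA model
#'
#' Recomputes the evidence lower bound at the fitted parameters and
#' variational posterior: closed-form KL to the GP prior plus a
#' reparameterized Monte Carlo estimate of the expected log-likelihood.
#' Bit-reproducible for a fixed seed.
#'
#' @param object A fitted `calcium_gpfa`.
#' @param n_mc Number of Monte Carlo samples.
#' @param seed RNG seed.
#' @return Scalar ELBO estimate.
#' @export
gpfa_elbo <- function(object, n_mc = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- object$y
  vals <- y$values
  p <- nrow(object$means); T <- ncol(vals)
  trials <- if (is.null(y$trial_ids)) list(seq_len(T))
            else split(seq_len(T), y$trial_ids)
  prior <- gp_prior_struct(length(trials[[1L]]), object$lengthscales)
  v <- object$scales^2
  kl <- 0
  for (j in seq_len(p)) for (ix in trials)
    kl <- kl + gp_kl(object$means[j, ix], v[j, ix], prior[[j]])$kl
  nl <- rate_fun(object$nonlinearity)
  if (object$obs == "calcium")
    delta <- ar_residual(y, object$obs_params)
  ell <- 0
  for (s in seq_len(n_mc)) {
    x <- object$means + object$scales * matrix(stats::rnorm(p * T), p, T)
    eta <- object$C %*% x + object$d
    ell <- ell + switch(object$obs,
      gaussian = sum(stats::dnorm(vals - eta, 0, sqrt(object$psi), log = TRUE)),
      poisson = sum(stats::dpois(vals, nl$f(eta) + 1e-10, log = TRUE)),
      # the training truncation defines the model's likelihood here
      calcium = sum(.calcium_marglik_cpp(delta, nl$f(eta) + 1e-10,
                                         object$obs_params$c,
                                         object$obs_params$sigma2,
                                         as.integer(object$max_count),
                                         FALSE)$ll)) / n_mc
  }
  ell - kl
}

# ---- Adam optimizer over a named list of arrays ------------------------

adam_new <- function(theta, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$mth <- lapply(theta, function(x) x * 0)
  e$vth <- lapply(theta, function(x) x * 0)
  e$t <- 0L
  e$b1 <- b1; e$b2 <- b2; e$eps <- eps
  e
}

adam_step <- function(opt, theta, grad, lr, maximize = FALSE, clip = 1e3) {
  opt$t <- opt$t + 1L
  gn <- sqrt(sum(vapply(grad, function(g) sum(g^2), numeric(1))))
  sc <- if (is.finite(gn) && gn > clip) clip / gn else 1
  for (nm in names(theta)) {
    g <- grad[[nm]] * sc * (if (maximize) 1 else -1)
    opt$mth[[nm]] <- opt$b1 * opt$mth[[nm]] + (1 - opt$b1) * g
    opt$vth[[nm]] <- opt$b2 * opt$vth[[nm]] + (1 - opt$b2) * g^2
    mhat <- opt$mth[[nm]] / (1 - opt$b1^opt$t)
    vhat <- opt$vth[[nm]] / (1 - opt$b2^opt$t)
    theta[[nm]] <- theta[[nm]] + lr * mhat / (sqrt(vhat) + opt$eps)
  }
  theta
}
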