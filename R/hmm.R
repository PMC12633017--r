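#' Forward-backward smoothing for an HMM
#'
#' Standard scaled forward-backward recursions given a matrix of per-bin,
#' per-state emission log-likelihoods. When `trial_ids` is supplied the
#' recursions restart at each trial boundary (trials are independent given
#' the parameters) and the returned `logZ` is the sum over trials.
#'
#' @param loglik T x K matrix of emission log-likelihoods.
#' @param pi0 Initial state distribution (length K).
#' @param P K x K row-stochastic transition matrix.
#' @param trial_ids Optional trial partition of the time axis.
#' @return A list with `gamma` (T x K posterior state marginals), `xi_sum`
#'   (K x K summed pairwise posteriors, within-trial transitions only),
#'   `start_counts` (summed gamma at trial starts), and `logZ` (marginal
#'   log-likelihood).
#' @export
forward_backward <- function(loglik, pi0, P, trial_ids = NULL) {
  loglik <- as.matrix(loglik)
  K <- ncol(loglik)
  stopifnot(length(pi0) == K, all(dim(P) == K))
  if (any(abs(rowSums(P) - 1) > 1e-8) || abs(sum(pi0) - 1) > 1e-8)
    stop("pi0 and rows of P must sum to 1")
  pieces <- if (is.null(trial_ids)) list(seq_len(nrow(loglik)))
            else split(seq_len(nrow(loglik)), trial_ids)
  gamma <- matrix(0, nrow(loglik), K)
  xi_sum <- matrix(0, K, K)
  start_counts <- numeric(K)
  logZ <- 0
  for (ix in pieces) {
    fb <- fb_single(loglik[ix, , drop = FALSE], pi0, P)
    gamma[ix, ] <- fb$gamma
    xi_sum <- xi_sum + fb$xi_sum
    start_counts <- start_counts + fb$gamma[1L, ]
    logZ <- logZ + fb$logZ
  }
  list(gamma = gamma, xi_sum = xi_sum, start_counts = start_counts, logZ = logZ)
}

fb_single <- function(ll, pi0, P) {
  T <- nrow(ll); K <- ncol(ll)
  mx <- apply(ll, 1L, max)
  if (!all(is.finite(mx)))
    stop("numerical failure: no state has positive likelihood at bin ",
         which(!is.finite(mx))[1L])
  b <- exp(ll - mx)
  alpha <- matrix(0, T, K); cs <- numeric(T)
  a <- pi0 * b[1L, ]
  cs[1L] <- sum(a); alpha[1L, ] <- a / cs[1L]
  if (T > 1L) for (t in 2:T) {
    a <- drop(alpha[t - 1L, ] %*% P) * b[t, ]
    cs[t] <- sum(a)
    if (cs[t] <= 0 || !is.finite(cs[t]))
      stop("numerical failure in forward pass at bin ", t)
    alpha[t, ] <- a / cs[t]
  }
  beta <- matrix(1, T, K)
  xi_sum <- matrix(0, K, K)
  if (T > 1L) for (t in (T - 1L):1L) {
    bb <- b[t + 1L, ] * beta[t + 1L, ]
    xi <- (alpha[t, ] %o% bb) * P
    xi_sum <- xi_sum + xi / sum(xi)
    beta[t, ] <- drop(P %*% bb) / cs[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi_sum = xi_sum, logZ = sum(log(cs)) + sum(mx))
}

viterbi_path <- function(loglik, pi0, P, trial_ids = NULL) {
  pieces <- if (is.null(trial_ids)) list(seq_len(nrow(loglik)))
            else split(seq_len(nrow(loglik)), trial_ids)
  out <- integer(nrow(loglik))
  lpi0 <- log(pi0); lP <- log(P)
  for (ix in pieces) out[ix] <- vit_single(loglik[ix, , drop = FALSE], lpi0, lP)
  out
}

vit_single <- function(ll, lpi0, lP) {
  T <- nrow(ll); K <- ncol(ll)
  d <- lpi0 + ll[1L, ]
  psi <- matrix(1L, T, K)
  if (T > 1L) for (t in 2:T) {
    m <- d + lP                       # m[i, j] = d[i] + log P[i, j]
    psi[t, ] <- apply(m, 2L, which.max)   # ties -> lower state index
    d <- m[cbind(psi[t, ], seq_len(K))] + ll[t, ]
  }
  path <- integer(T)
  path[T] <- which.max(d)
  if (T > 1L) for (t in (T - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

# ---- emission models ---------------------------------------------------

# Spike-count truncation for HMM likelihood evaluations: a fixed user choice,
# or adapted to the largest current rate estimate so the discarded Poisson
# tail is negligible.
hmm_truncation <- function(model) {
  if (!is.null(model$max_count) && !is.na(model$max_count))
    return(as.integer(model$max_count))
  as.integer(auto_max_count(max(model$rates)))
}

# model: list(obs, K, rates | mu/var | m, obs_params, max_count)
hmm_emission_logliks <- function(y, model) {
  vals <- y$values
  T <- ncol(vals); K <- model$K
  ll <- matrix(0, T, K)
  switch(model$obs,
    calcium = {
      delta <- ar_residual(y, model$obs_params)
      R <- hmm_truncation(model)
      for (k in seq_len(K)) {
        rk <- matrix(model$rates[k, ], nrow(vals), T)
        out <- .calcium_marglik_cpp(delta, rk, model$obs_params$c,
                                    model$obs_params$sigma2, R, FALSE)
        ll[, k] <- colSums(out$ll)
      }
    },
    gaussian = {
      # full covariance per state (ridge-regularized), evaluated via the
      # Cholesky factor
      N <- nrow(vals)
      for (k in seq_len(K)) {
        R <- chol(model$sigma[[k]])
        z <- backsolve(R, vals - model$mu[k, ], transpose = TRUE)
        ll[, k] <- -0.5 * (N * log(2 * pi) + colSums(z^2)) -
          sum(log(diag(R)))
      }
    },
    ar = {
      # shared per-neuron decay, state-dependent offsets: the calcium model
      # with the latent spiking replaced by a free per-state mean
      delta0 <- ar_residual(y, model$obs_params)
      s2 <- model$obs_params$sigma2
      for (k in seq_len(K)) {
        r <- delta0 - model$m[k, ]
        ll[, k] <- colSums(-0.5 * (log(2 * pi * s2) + r^2 / s2))
      }
    },
    poisson = {
      for (k in seq_len(K))
        ll[, k] <- colSums(stats::dpois(vals, model$rates[k, ], log = TRUE))
    },
    stop("unknown observation model: ", model$obs))
  ll
}

hmm_mstep_obs <- function(y, model, gamma) {
  vals <- y$values
  N <- nrow(vals); T <- ncol(vals); K <- model$K
  colw <- colSums(gamma)
  switch(model$obs,
    calcium = {
      delta <- ar_residual(y, model$obs_params)
      en_bar <- matrix(0, N, T); en2_bar <- matrix(0, N, T)
      rates <- model$rates
      R <- hmm_truncation(model)
      for (k in seq_len(K)) {
        rk <- matrix(model$rates[k, ], N, T)
        out <- .calcium_marglik_cpp(delta, rk, model$obs_params$c,
                                    model$obs_params$sigma2, R, TRUE)
        gk <- gamma[, k]
        rates[k, ] <- pmax(drop(out$en %*% gk) / colw[k], 1e-6)
        en_bar <- en_bar + out$en * rep(gk, each = N)
        en2_bar <- en2_bar + out$en2 * rep(gk, each = N)
      }
      model$rates <- rates
      model$obs_params <- update_calcium_obs(y, en_bar, en2_bar,
                                             model$obs_params,
                                             model$alpha_clip)
    },
    gaussian = {
      mu <- t((vals %*% gamma)) / colw           # K x N
      model$mu <- mu
      for (k in seq_len(K)) {
        r <- (vals - mu[k, ]) * rep(sqrt(gamma[, k]), each = N)
        model$sigma[[k]] <- tcrossprod(r) / colw[k] + 1e-6 * diag(N)
      }
    },
    ar = {
      # coordinate sweeps on the exact weighted least-squares objective:
      # shared slope alpha per neuron, per-state offsets, shared variance
      lag1 <- lag_stack(vals, 1L, y$trial_ids)[[1L]]
      alpha <- model$obs_params$alphas[, 1L]
      m <- model$m
      for (sweep in 1:3) {
        d0 <- vals - alpha * lag1
        m <- t(d0 %*% gamma) / colw              # K x N
        mbar <- t(m) %*% t(gamma)                # N x T expected offset
        num <- rowSums(lag1 * (vals - mbar))
        den <- rowSums(lag1^2)
        alpha <- ifelse(den > 0, num / den, alpha)
        alpha <- pmin(pmax(alpha, model$alpha_clip[1L]), model$alpha_clip[2L])
      }
      resid2 <- (vals - alpha * lag1 - t(m) %*% t(gamma))^2 +
        (t(m^2) %*% t(gamma)) - (t(m) %*% t(gamma))^2
      s2 <- pmax(rowMeans(resid2), 1e-8)
      model$m <- m
      model$obs_params <- calcium_params(alphas = alpha,
                                         c = model$obs_params$c,
                                         sigma2 = s2)
    },
    poisson = {
      model$rates <- pmax(t(vals %*% gamma) / colw, 1e-6)
    })
  model
}

# k-means based initialization; restart index r perturbs the clustering seed.
hmm_init <- function(y, K, obs, ar_order, alpha_clip, max_count, r) {
  vals <- y$values
  N <- nrow(vals); T <- ncol(vals)
  sm <- t(apply(vals, 1L, function(v) {
    f <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    f[is.na(f)] <- v[is.na(f)]
    f
  }))
  km <- tryCatch(stats::kmeans(t(sm), centers = K, nstart = 2, iter.max = 30),
                 error = function(e) NULL)
  labels <- if (is.null(km)) sample.int(K, T, replace = TRUE) else km$cluster
  # transition counts with smoothing, within trials only
  starts <- if (is.null(y$trial_ids)) 1L else
    c(1L, which(diff(y$trial_ids) != 0L) + 1L)
  P <- matrix(1, K, K)
  if (T > 1L) for (t in 2:T) if (!(t %in% starts))
    P[labels[t - 1L], labels[t]] <- P[labels[t - 1L], labels[t]] + 1
  P <- P / rowSums(P)
  pi0 <- (tabulate(labels[starts], K) + 0.5)
  pi0 <- pi0 / sum(pi0)
  model <- list(obs = obs, K = K, alpha_clip = alpha_clip, max_count = max_count)
  if (obs == "calcium") {
    op <- suppressWarnings(init_neuron_params(y, ar_order = ar_order))
    cvec <- pmin(pmax(stats::rnorm(N, 1, 0.2), 0.4), 2.5)
    op <- calcium_params(op$alphas, c = cvec, sigma2 = pmax(op$sigma2, 1e-4))
    if (ar_order == 1L && !is.null(alpha_clip))
      op$alphas[, 1L] <- pmin(pmax(op$alphas[, 1L], alpha_clip[1L]), alpha_clip[2L])
    en0 <- pmax(ar_residual(y, op), 0) / op$c
    rates <- matrix(0, K, N)
    for (k in seq_len(K))
      rates[k, ] <- pmax(rowMeans(en0[, labels == k, drop = FALSE]), 0.01)
    model$obs_params <- op
    model$rates <- rates
  } else if (obs == "gaussian") {
    mu <- matrix(0, K, N)
    sigma <- vector("list", K)
    for (k in seq_len(K)) {
      sel <- vals[, labels == k, drop = FALSE]
      mu[k, ] <- rowMeans(sel)
      va <- pmax(apply(sel, 1L, stats::var), 1e-4)
      va[is.na(va)] <- 1e-2
      sigma[[k]] <- diag(va, N)
    }
    model$mu <- mu; model$sigma <- sigma
  } else if (obs == "ar") {
    op <- suppressWarnings(init_neuron_params(y, ar_order = 1L))
    op$alphas[, 1L] <- pmin(pmax(op$alphas[, 1L], alpha_clip[1L]),
                            alpha_clip[2L])
    op$sigma2 <- pmax(op$sigma2, 1e-4)
    d0 <- ar_residual(y, op)
    m <- matrix(0, K, N)
    for (k in seq_len(K)) m[k, ] <- rowMeans(d0[, labels == k, drop = FALSE])
    model$obs_params <- op
    model$m <- m
  } else if (obs == "poisson") {
    rates <- matrix(0, K, N)
    for (k in seq_len(K))
      rates[k, ] <- pmax(rowMeans(vals[, labels == k, drop = FALSE]), 1e-3)
    model$rates <- rates
  }
  model$pi0 <- pi0
  model$P <- P
  model
}

#' Fit a hidden Markov model to calcium traces or spike counts
#'
#' Fits a K-state HMM by expectation-maximization under one of four
#' observation models: `"calcium"` (the spike-marginalized Poisson-AR
#' fluorescence likelihood; each state carries per-neuron Poisson rates and
#' the AR/influx/noise parameters are shared across states), `"gaussian"`
#' (time-independent Gaussian emissions with state-dependent mean and full
#' covariance), `"ar"` (AR(1) Gaussian emissions with shared per-neuron
#' decay and state-dependent offsets, i.e. the calcium model with the
#' latent spiking component ablated), and `"poisson"` (Poisson emissions,
#' for fitting spike-count data directly; `y` is then a count matrix).
#'
#' The E-step marginalizes the latent spike counts numerically to obtain
#' state-dependent likelihoods. The M-step updates the initial distribution
#' and transition matrix in closed form from the expected sufficient
#' statistics, and uses exact conditional-maximization updates (via the
#' posterior moments of the latent spike counts) for the rates and
#' observation parameters, so the marginal likelihood is non-decreasing.
#' Initialization is by k-means clustering of (smoothed) observation columns;
#' `restarts` perturbed replicates are fitted and the best final training
#' likelihood is kept.
#'
#' @param y A `trace_set` or neurons-by-time matrix (for `obs = "poisson"`, a
#'   nonnegative integer count matrix).
#' @param K Number of discrete states.
#' @param obs Observation model (see Details).
#' @param ar_order AR order of the calcium observation model.
#' @param n_iter Maximum EM iterations.
#' @param tol Relative log-likelihood improvement below which EM stops.
#' @param restarts Number of perturbed k-means restarts.
#' @param alpha_clip Clipping bounds for the AR(1) coefficient.
#' @param max_count Spike-count truncation (`NULL` = automatic).
#' @param init Optional warm start: a list with `pi0`, `P` and the
#'   observation fields (`rates` and `obs_params` for `"calcium"`;
#'   `mu`/`sigma` for `"gaussian"`; `m`/`obs_params` for `"ar"`; `rates`
#'   for `"poisson"`). When given, k-means restarts are skipped.
#' @param init_states Optional integer state sequence (length = number of
#'   bins) used as a known-label warm start: emissions are first fitted with
#'   the labels fixed, then full EM runs from there.
#' @param seed Optional RNG seed (controls initialization randomness).
#' @param verbose Print per-iteration log-likelihoods.
#' @return An object of class `calcium_hmm` with components `pi0`, `P`,
#'   `rates` (or `mu`/`var`/`m` for the baselines), `obs_params`, `loglik`,
#'   `loglik_trace`, `gamma`, `states` (Viterbi path on the training data).
#' @examples
#' sim <- simulate_chain_hmm(n_time = 300, seed = 1)
#' fit <- calcium_hmm(sim$train, K = 5, n_iter = 15, restarts = 1, seed = 1)
#' align_states(sim$train_states, predict(fit, type = "states"), K = 5)$rho
#' @export
calcium_hmm <- function(y, K, obs = c("calcium", "gaussian", "ar", "poisson"),
                        ar_order = 1L, n_iter = 50L, tol = 1e-6,
                        restarts = 3L, alpha_clip = c(0.6, 0.95),
                        max_count = NULL, init = NULL, init_states = NULL,
                        seed = NULL, verbose = FALSE) {
  obs <- match.arg(obs)
  y <- as_trace_set(y)
  if (obs == "poisson" && any(y$values != round(y$values)))
    stop("obs = 'poisson' expects integer spike counts as data")
  if (K < 1L) stop("K must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(init)) {
    model <- c(list(obs = obs, K = K, alpha_clip = alpha_clip,
                    max_count = max_count),
               init[intersect(names(init),
                              c("pi0", "P", "rates", "mu", "sigma", "m",
                                "obs_params"))])
    best <- hmm_em(y, model, n_iter, tol, verbose)
  } else if (!is.null(init_states)) {
    model <- hmm_init(y, K, obs, ar_order, alpha_clip, max_count, 1L)
    # fit emissions with the provided labels fixed (hard E-step), then EM
    gamma_fix <- matrix(0, ncol(y$values), K)
    gamma_fix[cbind(seq_len(ncol(y$values)), as.integer(init_states))] <- 1
    for (it in 1:3) model <- hmm_mstep_obs(y, model, gamma_fix)
    best <- hmm_em(y, model, n_iter, tol, verbose)
  } else {
    best <- NULL
    for (r in seq_len(restarts)) {
      model <- hmm_init(y, K, obs, ar_order, alpha_clip, max_count, r)
      fit <- hmm_em(y, model, n_iter, tol, verbose)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  }
  ll <- hmm_emission_logliks(y, best$model)
  fb <- forward_backward(ll, best$model$pi0, best$model$P, y$trial_ids)
  out <- c(best$model,
           list(loglik = fb$logZ, loglik_trace = best$trace,
                gamma = fb$gamma,
                states = viterbi_path(ll, best$model$pi0, best$model$P,
                                      y$trial_ids),
                n_neurons = nrow(y$values), n_time = ncol(y$values),
                trial_ids = y$trial_ids, dt = y$dt, call = match.call()))
  class(out) <- "calcium_hmm"
  out
}

hmm_em <- function(y, model, n_iter, tol, verbose) {
  trace <- numeric(0)
  for (it in seq_len(n_iter)) {
    ll <- hmm_emission_logliks(y, model)
    fb <- forward_backward(ll, model$pi0, model$P, y$trial_ids)
    trace <- c(trace, fb$logZ)
    if (verbose) message(sprintf("  EM iter %3d  logLik %.4f", it, fb$logZ))
    if (it > 1L) {
      d <- fb$logZ - trace[it - 1L]
      if (d < -(tol * abs(fb$logZ) + 1e-6))
        warning(sprintf("log-likelihood decreased at EM iteration %d (%.3g)",
                        it, d))
      if (abs(d) < tol * abs(fb$logZ)) break
    }
    model$pi0 <- (fb$start_counts + 1e-8) / sum(fb$start_counts + 1e-8)
    Pn <- fb$xi_sum + 1e-8
    model$P <- Pn / rowSums(Pn)
    model <- hmm_mstep_obs(y, model, fb$gamma)
  }
  list(model = model, loglik = trace[length(trace)], trace = trace)
}

#' @export
print.calcium_hmm <- function(x, ...) {
  cat(sprintf("<calcium_hmm> K = %d states, %d neurons, obs = '%s'\n",
              x$K, x$n_neurons, x$obs))
  cat(sprintf("  logLik %.2f after %d EM iterations\n",
              x$loglik, length(x$loglik_trace)))
  invisible(x)
}

#' @export
summary.calcium_hmm <- function(object, ...) {
  print(object)
  cat("  transition matrix:\n")
  print(round(object$P, 3))
  if (!is.null(object$rates)) {
    cat("  per-state mean rate (spikes/bin):\n")
    print(round(rowMeans(object$rates), 4))
  }
  if (!is.null(object$obs_params)) print(object$obs_params)
  invisible(object)
}

#' @export
logLik.calcium_hmm <- function(object, ...) {
  K <- object$K; N <- object$n_neurons
  df <- (K - 1) + K * (K - 1) + switch(object$obs,
    calcium = K * N + N * (ar_order(object$obs_params) + 2),
    gaussian = K * N + K * N * (N + 1) / 2,
    ar = K * N + 2 * N,
    poisson = K * N)
  structure(object$loglik, df = df, class = "logLik")
}

#' @export
coef.calcium_hmm <- function(object, ...) {
  out <- list(pi0 = object$pi0, P = object$P)
  for (f in c("rates", "mu", "sigma", "m", "obs_params"))
    if (!is.null(object[[f]])) out[[f]] <- object[[f]]
  out
}

#' Posterior inference on new data from a fitted HMM
#'
#' @param object A fitted `calcium_hmm`.
#' @param newdata Optional `trace_set`/matrix; default uses the training data
#'   quantities stored in the fit.
#' @param type `"states"` (Viterbi path), `"gamma"` (posterior marginals),
#'   `"loglik"` (marginal log-likelihood of the data), or `"emissions"`
#'   (T x K emission log-likelihood matrix).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.calcium_hmm <- function(object, newdata = NULL,
                                type = c("states", "gamma", "loglik",
                                         "emissions"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "states") return(object$states)
    if (type == "gamma") return(object$gamma)
    if (type == "loglik") return(object$loglik)
  }
  y <- if (is.null(newdata)) stop("stored emissions unavailable; pass newdata")
       else as_trace_set(newdata)
  ll <- hmm_emission_logliks(y, object)
  switch(type,
    states = viterbi_path(ll, object$pi0, object$P, y$trial_ids),
    gamma = forward_backward(ll, object$pi0, object$P, y$trial_ids)$gamma,
    loglik = forward_backward(ll, object$pi0, object$P, y$trial_ids)$logZ,
    emissions = ll)
}

#' Simulate data from a fitted HMM
#'
#' @param object A fitted `calcium_hmm`.
#' @param nsim Number of time bins to simulate.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list with `states`, `spikes` (when the model has rates) and
#'   `y` (a `trace_set` for the calcium model, a matrix otherwise).
#' @export
simulate.calcium_hmm <- function(object, nsim = 1000L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- object$K
  states <- integer(nsim)
  states[1L] <- sample.int(K, 1L, prob = object$pi0)
  for (t in seq_len(nsim - 1L))
    states[t + 1L] <- sample.int(K, 1L, prob = object$P[states[t], ])
  out <- list(states = states)
  if (object$obs %in% c("calcium", "poisson")) {
    lam <- t(object$rates[states, , drop = FALSE])      # N x T
    spikes <- matrix(stats::rpois(length(lam), lam), nrow(lam))
    out$spikes <- spikes
    out$y <- if (object$obs == "calcium")
      sample_trace(spikes, object$obs_params, dt = object$dt) else spikes
  } else if (object$obs == "gaussian") {
    N <- object$n_neurons
    yv <- matrix(0, N, nsim)
    for (t in seq_len(nsim)) {
      R <- chol(object$sigma[[states[t]]])
      yv[, t] <- object$mu[states[t], ] + drop(crossprod(R, stats::rnorm(N)))
    }
    out$y <- yv
  } else if (object$obs == "ar") {
    N <- object$n_neurons
    alpha <- object$obs_params$alphas[, 1L]
    sdv <- sqrt(object$obs_params$sigma2)
    yv <- matrix(0, N, nsim)
    for (t in seq_len(nsim)) {
      prev <- if (t > 1L) yv[, t - 1L] else 0
      yv[, t] <- alpha * prev + object$m[states[t], ] +
        stats::rnorm(N, sd = sdv)
    }
    out$y <- trace_set(yv, dt = object$dt)
  }
  out
}

#' Select the number of HMM states by held-out likelihood
#'
#' Fits an HMM for each candidate K on the training data and scores it by the
#' marginal log-likelihood of held-out data, the standard cross-validation
#' protocol for choosing the number of discrete states.
#'
#' @param y_train,y_test Training and held-out data (`trace_set` or matrix).
#' @param K_range Integer vector of candidate state counts.
#' @param ... Passed on to [calcium_hmm()] (`obs`, `restarts`, `n_iter`, ...).
#' @param seed Optional RNG seed.
#' @return An object of class `state_selection`: data frame `table` with
#'   columns `K`, `train_loglik`, `test_loglik`; `best_K`; and `fits` (the
#'   fitted models).
#' @export
select_num_states <- function(y_train, y_test, K_range, ..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fits <- list(); rows <- NULL
  for (K in K_range) {
    fit <- calcium_hmm(y_train, K = K, ...)
    test_ll <- predict(fit, newdata = y_test, type = "loglik")
    fits[[as.character(K)]] <- fit
    rows <- rbind(rows, data.frame(K = K, train_loglik = fit$loglik,
                                   test_loglik = test_ll))
  }
  structure(list(table = rows, best_K = rows$K[which.max(rows$test_loglik)],
                 fits = fits),
            class = "state_selection")
}

#' @export
print.state_selection <- function(x, ...) {
  cat("<state_selection> held-out log-likelihood by K:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("best K = %d\n", x$best_K))
  invisible(x)
}

#' Occupancy curve statistics for a discrete state
#'
#' Computes, per time bin, the fraction of trials whose state path is in
#' `target_state`, then reports the time of the peak of the (lightly
#' smoothed) occupancy curve and its full width at half maximum: the duration
#' of the contiguous block around the peak where the smoothed curve is at
#' least half its maximum.
#'
#' @param paths Matrix (trials x time) of integer state paths, or a list of
#'   equal-length path vectors.
#' @param target_state The state of interest.
#' @param dt Bin width in seconds.
#' @param smooth Moving-average window (bins) applied before the peak/width
#'   computation; use 1 for no smoothing.
#' @return A list of class `occupancy_stats`: `peak_time` (s), `width` (s,
#'   FWHM), `curve` (raw occupancy), `smoothed`.
#' @export
occupancy_stats <- function(paths, target_state, dt = 1, smooth = 3L) {
  if (is.list(paths)) paths <- do.call(rbind, paths)
  occ <- colMeans(paths == target_state)
  if (all(occ == 0)) stop("state ", target_state, " is never visited")
  sm <- if (smooth > 1L) {
    pad <- c(rep(occ[1L], smooth), occ, rep(occ[length(occ)], smooth))
    f <- stats::filter(pad, rep(1 / smooth, smooth), sides = 2)
    as.numeric(f[(smooth + 1L):(smooth + length(occ))])
  } else occ
  peak <- which.max(sm)
  half <- sm[peak] / 2
  above <- sm >= half
  lo <- peak; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- peak; while (hi < length(sm) && above[hi + 1L]) hi <- hi + 1L
  structure(list(peak_time = (peak - 1L) * dt, width = (hi - lo + 1L) * dt,
                 curve = occ, smoothed = sm, dt = dt),
            class = "occupancy_stats")
}

#' @export
print.occupancy_stats <- function(x, ...) {
  cat(sprintf("<occupancy_stats> peak at %.2f s, FWHM %.2f s\n",
              x$peak_time, x$width))
  invisible(x)
}
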