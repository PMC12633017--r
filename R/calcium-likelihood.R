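#' Autoregressive prediction residual of fluorescence traces
#'
#' Computes `delta_t = y_t - sum_j alpha_j y_{t-j}`, the innovation of the
#' AR(p) fluorescence process. Under the observation model the residual in a
#' bin equals `c * n_t` plus Gaussian noise, where `n_t` is the (unobserved)
#' spike count, so all likelihood evaluations reduce to a Poisson-Gaussian
#' mixture density over `delta`. Lags reaching before the first bin of the
#' recording (or of each trial, when `y` is trial-structured) are treated as
#' zero, consistent with a dF/F baseline of zero.
#'
#' @param y A `trace_set` or neurons-by-time matrix.
#' @param params A [calcium_params()] object.
#' @return Numeric matrix of residuals, same shape as the trace matrix.
#' @export
ar_residual <- function(y, params) {
  y <- as_trace_set(y)
  p <- ar_order(params)
  if (ncol(y$values) < p + 1L)
    stop("need at least p + 1 time bins for an AR(p) residual")
  if (nrow(y$values) != n_neurons(params))
    stop("trace and parameter neuron counts differ")
  lags <- lag_stack(y$values, p, y$trial_ids)
  delta <- y$values
  for (j in seq_len(p)) delta <- delta - params$alphas[, j] * lags[[j]]
  delta
}

# List of p lagged copies of vals (neurons x time), zero-padded at the start
# of the recording and at every trial boundary.
lag_stack <- function(vals, p, trial_ids = NULL) {
  T <- ncol(vals)
  starts <- if (is.null(trial_ids)) 1L else
    c(1L, which(diff(trial_ids) != 0L) + 1L)
  lags <- vector("list", p)
  for (j in seq_len(p)) {
    lj <- matrix(0, nrow(vals), T)
    if (T > j) lj[, (j + 1L):T] <- vals[, 1L:(T - j), drop = FALSE]
    # zero out lags that would cross a trial boundary
    for (s in starts) {
      idx <- s:min(T, s + j - 1L)
      lj[, idx] <- 0
    }
    lags[[j]] <- lj
  }
  lags
}

# Truncation point for the spike-count sum: covers the Poisson bulk and the
# counts implied by the largest residual.
auto_max_count <- function(lambda_max, default = 10L) {
  max(default, ceiling(lambda_max + 10 * sqrt(max(lambda_max, 0))))
}

#' Marginalized calcium log-likelihood
#'
#' Evaluates, per neuron and bin, the log-density of the fluorescence
#' innovation under the spike-marginalized observation model:
#' `log sum_{n=0}^{R} N(delta_t; c n, sigma2) Poisson(n; lambda_t)`,
#' computed in log space via log-sum-exp. The latent Poisson spike count is
#' summed out up to a truncation `max_count`; with the default (`NULL`) the
#' truncation adapts to the largest rate so that the discarded Poisson tail
#' mass is negligible.
#'
#' @param y A `trace_set` or neurons-by-time matrix.
#' @param rates Nonnegative matrix of expected spikes per bin, same shape as
#'   the trace matrix (a scalar or per-neuron vector is recycled).
#' @param params A [calcium_params()] object.
#' @param max_count Spike-count truncation R (`NULL` = automatic).
#' @param moments If `TRUE`, also return the posterior count moments
#'   `E[n | delta]` and `E[n^2 | delta]` per bin, used by the model-fitting
#'   routines.
#' @return A list with `per_bin` (neurons x time log-likelihood matrix),
#'   `total` (their sum), `max_count`, and when requested `en`, `en2`.
#' @examples
#' cp <- calcium_params(alphas = 0.8, c = 1, sigma2 = 0.01)
#' y <- matrix(c(0, 1, 0.8, 0.64), 1)  # one spike then pure decay
#' calcium_loglik(y, rates = 0.2, params = cp)$total
#' @export
calcium_loglik <- function(y, rates, params, max_count = NULL, moments = FALSE) {
  y <- as_trace_set(y)
  N <- nrow(y$values); T <- ncol(y$values)
  if (is.matrix(rates)) {
    if (!all(dim(rates) == c(N, T))) stop("rate matrix shape mismatch")
  } else {
    rates <- matrix(rep_len(as.numeric(rates), N), N, T)
  }
  if (any(rates < 0) || !all(is.finite(rates)))
    stop("rates must be finite and nonnegative")
  lmax <- max(rates)
  if (is.null(max_count)) {
    max_count <- auto_max_count(lmax)
  } else {
    if (max_count < 1L) stop("max_count must be >= 1")
    tail_mass <- stats::ppois(max_count, lmax, lower.tail = FALSE)
    if (tail_mass > 1e-8)
      warning(sprintf(
        "spike-count truncation R = %d discards Poisson tail mass %.2e at the largest rate %.3g",
        as.integer(max_count), tail_mass, lmax))
  }
  delta <- ar_residual(y, params)
  out <- .calcium_marglik_cpp(delta, rates, params$c, params$sigma2,
                              as.integer(max_count), moments)
  res <- list(per_bin = out$ll, total = sum(out$ll),
              max_count = as.integer(max_count))
  if (moments) { res$en <- out$en; res$en2 <- out$en2 }
  res
}

#' Simulate fluorescence traces from spike counts
#'
#' Pushes integer spike counts through the AR(p) fluorescence recursion:
#' process noise of variance `sigma2` is injected inside the recursion (it is
#' filtered by the AR dynamics), while `noise_sd_extra` adds independent
#' measurement noise per bin on top of the generated trace, outside the
#' recursion. The measurement noise emulates shot/readout noise of the
#' microscope and is deliberately not part of the fitted generative model.
#'
#' @param spikes Nonnegative integer matrix, neurons x time.
#' @param params A [calcium_params()] object.
#' @param noise_sd_extra Standard deviation of additive measurement noise.
#' @param dt Bin width (seconds) recorded in the returned `trace_set`.
#' @param trial_ids Optional trial partition; the AR recursion restarts at
#'   zero at each trial boundary.
#' @param seed Optional RNG seed for reproducibility.
#' @return A `trace_set`.
#' @export
sample_trace <- function(spikes, params, noise_sd_extra = 0, dt = 1,
                         trial_ids = NULL, seed = NULL) {
  spikes <- as.matrix(spikes)
  if (any(spikes < 0) || any(spikes != round(spikes)))
    stop("spikes must be nonnegative integers")
  if (noise_sd_extra < 0) stop("noise_sd_extra must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  storage.mode(spikes) <- "integer"
  N <- nrow(spikes); T <- ncol(spikes)
  sd_proc <- sqrt(params$sigma2)
  eps <- matrix(stats::rnorm(N * T), N, T) * sd_proc
  if (is.null(trial_ids)) {
    vals <- .ar_filter_spikes_cpp(spikes, params$alphas, params$c, eps)
  } else {
    vals <- matrix(0, N, T)
    for (ix in split(seq_len(T), trial_ids))
      vals[, ix] <- .ar_filter_spikes_cpp(spikes[, ix, drop = FALSE],
                                          params$alphas, params$c,
                                          eps[, ix, drop = FALSE])
  }
  if (noise_sd_extra > 0)
    vals <- vals + matrix(stats::rnorm(N * T, sd = noise_sd_extra), N, T)
  trace_set(vals, dt = dt, trial_ids = trial_ids)
}

#' Heuristic per-neuron initialization of calcium observation parameters
#'
#' Estimates, independently per neuron: the AR coefficients by least-squares
#' regression of each observation on its lags (optionally restricted to decay
#' segments, bins where the trace decreases); the noise variance as the mean
#' squared residual of that regression; and the influx `c` by a grid sweep
#' choosing the value that best aligns the positive one-step increments of
#' the trace with the quantized levels `{0, c, 2c, 3c}`.
#'
#' @param y A `trace_set` or neurons-by-time matrix.
#' @param ar_order AR order p (1 or 2 are typical).
#' @param c_grid Candidate influx values for the grid sweep.
#' @param decay_only If `TRUE`, fit the AR regression only on bins where the
#'   trace decreases (so spike-driven jumps do not bias the decay estimate).
#' @return A [calcium_params()] object.
#' @export
init_neuron_params <- function(y, ar_order = 1L,
                               c_grid = seq(0.8, 2.2, by = 0.01),
                               decay_only = FALSE) {
  y <- as_trace_set(y)
  vals <- y$values
  p <- as.integer(ar_order)
  N <- nrow(vals); T <- ncol(vals)
  if (T < 10L * p) stop("need at least 10 * p bins for initialization")
  lags <- lag_stack(vals, p, y$trial_ids)
  alphas <- matrix(0, N, p)
  cvec <- numeric(N); s2 <- numeric(N)
  fallback_alpha <- c(0.8, rep(0, p - 1L))
  for (i in seq_len(N)) {
    yi <- vals[i, ]
    X <- vapply(lags, function(l) l[i, ], numeric(T))
    keep <- seq.int(p + 1L, T)
    if (decay_only) keep <- keep[yi[keep] < X[keep, 1L]]
    if (length(keep) < 5L * p || stats::sd(yi) < 1e-12) {
      d1 <- diff(yi)
      alphas[i, ] <- fallback_alpha
      cvec[i] <- 1.0
      s2[i] <- max(stats::var(d1), 1e-8)
      warning(sprintf("neuron %d: degenerate trace, using default parameters", i))
      next
    }
    Xk <- X[keep, , drop = FALSE]
    fit <- stats::lsfit(Xk, yi[keep], intercept = FALSE)
    alphas[i, ] <- fit$coefficients
    s2[i] <- max(mean(fit$residuals^2), 1e-8)
    inc <- diff(yi)
    inc <- inc[inc > 0]
    if (length(inc) == 0L) {
      cvec[i] <- 1.0
    } else {
      cost <- vapply(c_grid, function(cc) {
        q <- outer(inc, cc * 0:3, "-")^2
        sum(apply(q, 1L, min))
      }, numeric(1))
      cvec[i] <- c_grid[which.min(cost)]
    }
  }
  calcium_params(alphas = alphas, c = cvec, sigma2 = s2)
}

#' Maximum-likelihood fit of calcium observation parameters and a constant rate
#'
#' Fits `(alpha, c, sigma2, lambda)` per neuron by expectation-conditional
#' maximization: the E-step computes the posterior moments of the latent
#' spike count per bin, after which every update is closed-form (lambda from
#' expected counts; alpha and c jointly by weighted least squares; sigma2
#' from expected squared innovations). The marginal likelihood is
#' non-decreasing across iterations.
#'
#' @param y A `trace_set` or neurons-by-time matrix.
#' @param init Optional [calcium_params()] starting point (default: heuristic
#'   initialization).
#' @param lambda_init Initial rate (spikes/bin), recycled over neurons.
#' @param n_iter Maximum ECM iterations.
#' @param tol Stop when the total log-likelihood improves by less than this.
#' @param alpha_clip Bounds applied to the AR(1) coefficient during fitting
#'   (`NULL` for no clipping; ignored for p > 1).
#' @return A list with `params` ([calcium_params()]), `lambda` (per-neuron
#'   rate), `loglik` (trace of total log-likelihood per iteration).
#' @export
fit_calcium_neuron <- function(y, init = NULL, lambda_init = 0.2,
                               n_iter = 100L, tol = 1e-8,
                               alpha_clip = c(0.6, 0.95)) {
  y <- as_trace_set(y)
  if (is.null(init)) init <- init_neuron_params(y)
  params <- init
  N <- nrow(y$values)
  lambda <- rep_len(lambda_init, N)
  ll_trace <- numeric(0)
  for (it in seq_len(n_iter)) {
    rates <- matrix(lambda, N, ncol(y$values))
    ml <- calcium_loglik(y, rates, params, moments = TRUE)
    ll_trace <- c(ll_trace, ml$total)
    if (it > 1L && ml$total - ll_trace[it - 1L] < tol) break
    lambda <- pmax(rowMeans(ml$en), 1e-6)
    params <- update_calcium_obs(y, ml$en, ml$en2, params, alpha_clip)
  }
  list(params = params, lambda = lambda, loglik = ll_trace)
}

# Closed-form conditional-maximization update of (alpha, c, sigma2) given
# per-bin posterior count moments en, en2 (already weighted/averaged over any
# discrete states). Solves the (p+1)-dim normal equations per neuron, clips
# the AR(1) coefficient if requested, then re-solves c and updates sigma2.
update_calcium_obs <- function(y, en, en2, params, alpha_clip = NULL) {
  y <- as_trace_set(y)
  vals <- y$values
  p <- ar_order(params)
  N <- nrow(vals); T <- ncol(vals)
  lags <- lag_stack(vals, p, y$trial_ids)
  alphas <- params$alphas; cvec <- params$c; s2 <- params$sigma2
  for (i in seq_len(N)) {
    X <- vapply(lags, function(l) l[i, ], numeric(T))  # T x p
    yi <- vals[i, ]; eni <- en[i, ]; en2i <- en2[i, ]
    A <- crossprod(X)                       # p x p
    b1 <- crossprod(X, yi)                  # p
    v <- crossprod(X, eni)                  # p
    m2 <- sum(en2i); m1y <- sum(eni * yi)
    M <- rbind(cbind(A, v), c(v, m2))
    rhs <- c(b1, m1y)
    beta <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(beta)) next
    a_new <- beta[seq_len(p)]
    if (p == 1L && !is.null(alpha_clip))
      a_new <- min(max(a_new, alpha_clip[1L]), alpha_clip[2L])
    c_new <- if (m2 > 0) (m1y - sum(v * a_new)) / m2 else cvec[i]
    c_new <- max(c_new, 1e-4)
    pred <- drop(X %*% a_new)
    d <- yi - pred
    s2_new <- mean(d^2 - 2 * c_new * d * eni + c_new^2 * en2i)
    alphas[i, ] <- a_new
    cvec[i] <- c_new
    s2[i] <- max(s2_new, 1e-10)
  }
  calcium_params(alphas = alphas, c = cvec, sigma2 = s2)
}
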