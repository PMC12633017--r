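#' @useDynLib calatent, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimum-cost assignment (Hungarian algorithm, O(n^3) shortest augmenting
# path with potentials). Returns perm with perm[j] = row assigned to column j.
# Written here because no assignment-problem solver ships with base R.
assign_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials, index 1 = virtual column
  p <- integer(n + 1L)       # p[j]: row matched to column j-1 (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i; j0 <- 1L
    minv <- rep(Inf, n + 1L); used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in which(!used)) {
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      ui <- which(used)
      u[p[ui]] <- u[p[ui]] + delta
      v[ui] <- v[ui] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  p[2:(n + 1L)]
}

#' Align inferred discrete states to ground truth
#'
#' State labels of a fitted HMM are arbitrary up to permutation. This finds
#' the label permutation maximizing agreement with the true sequence (maximum
#' weight assignment on the confusion matrix, Hungarian algorithm), relabels
#' the inferred sequence, and reports the Pearson correlation between the
#' aligned integer label sequences together with the per-bin agreement
#' fraction. The correlation is meaningful when states have an ordinal
#' arrangement (as in sequential chain dynamics); the agreement fraction is
#' reported alongside as an ordering-free score.
#'
#' @param true_seq,inferred_seq Integer state sequences (values in `1:K`),
#'   same length.
#' @param K Number of states.
#' @return A list of class `state_alignment`: `permutation` (index j of the
#'   true label assigned to inferred label j), `aligned` (relabeled inferred
#'   sequence), `rho` (Pearson correlation), `agreement` (fraction equal).
#' @examples
#' s <- c(1, 1, 2, 2, 3, 3)
#' align_states(s, c(3, 3, 1, 1, 2, 2), K = 3)$rho
#' @export
align_states <- function(true_seq, inferred_seq, K) {
  true_seq <- as.integer(true_seq); inferred_seq <- as.integer(inferred_seq)
  if (length(true_seq) != length(inferred_seq))
    stop("sequences must have equal length")
  if (any(c(true_seq, inferred_seq) < 1L) || any(c(true_seq, inferred_seq) > K))
    stop("state labels must lie in 1..K")
  conf <- matrix(0, K, K)  # rows: true, cols: inferred
  for (t in seq_along(true_seq))
    conf[true_seq[t], inferred_seq[t]] <- conf[true_seq[t], inferred_seq[t]] + 1
  perm <- assign_min(max(conf) - conf)
  aligned <- perm[inferred_seq]
  rho <- if (stats::sd(true_seq) == 0 || stats::sd(aligned) == 0) {
    if (all(aligned == true_seq)) 1 else 0
  } else stats::cor(true_seq, aligned)
  structure(list(permutation = perm, aligned = aligned, rho = rho,
                 agreement = mean(aligned == true_seq), confusion = conf),
            class = "state_alignment")
}

#' @export
print.state_alignment <- function(x, ...) {
  cat(sprintf("<state_alignment> rho = %.3f, agreement = %.3f\n",
              x$rho, x$agreement))
  invisible(x)
}

#' Align inferred continuous latents to ground truth by affine regression
#'
#' Latent trajectories recovered by factor models are identified only up to
#' an invertible affine transform. This regresses the true latents on the
#' inferred ones (least squares with intercept, pooled over all time bins and
#' trials) and scores the aligned reconstruction by per-dimension and mean
#' R-squared and mean squared error. When `trial_ids` is given, per-trial
#' R-squared values under the pooled alignment are also returned.
#'
#' @param true_latents Numeric matrix p x T of ground-truth latents.
#' @param inferred Numeric matrix q x T of inferred latents.
#' @param trial_ids Optional trial partition of the time axis.
#' @return A list of class `latent_alignment`: `weights` ((q+1) x p affine
#'   map, intercept first), `fitted` (p x T aligned reconstruction), `r2`
#'   (per true dimension), `mean_r2`, `mse`, and optionally `per_trial_r2`.
#' @export
align_latents <- function(true_latents, inferred, trial_ids = NULL) {
  X <- t(as.matrix(inferred)); Y <- t(as.matrix(true_latents))  # T x q, T x p
  if (nrow(X) != nrow(Y)) stop("latent time axes differ")
  Xd <- cbind(1, X)
  XtX <- crossprod(Xd)
  w <- tryCatch(solve(XtX, crossprod(Xd, Y)), error = function(e) NULL)
  if (is.null(w)) {
    warning("rank-deficient inferred latents; using ridge fallback (1e-6)")
    w <- solve(XtX + 1e-6 * diag(nrow(XtX)), crossprod(Xd, Y))
  }
  fit <- Xd %*% w
  ss_res <- colSums((Y - fit)^2)
  ss_tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- 1 - ss_res / ss_tot
  out <- list(weights = w, fitted = t(fit), r2 = r2, mean_r2 = mean(r2),
              mse = mean((Y - fit)^2))
  if (!is.null(trial_ids)) {
    out$per_trial_r2 <- vapply(split(seq_len(nrow(Y)), trial_ids), function(ix) {
      yi <- Y[ix, , drop = FALSE]; fi <- fit[ix, , drop = FALSE]
      1 - sum((yi - fi)^2) / sum(sweep(yi, 2, colMeans(yi))^2)
    }, numeric(1))
  }
  class(out) <- "latent_alignment"
  out
}

#' @export
print.latent_alignment <- function(x, ...) {
  cat(sprintf("<latent_alignment> mean R^2 = %.3f (per-dim: %s), MSE = %.4g\n",
              x$mean_r2, paste(sprintf("%.3f", x$r2), collapse = ", "), x$mse))
  invisible(x)
}

#' Tabulate model-comparison metrics across seeds
#'
#' Aggregates a long table of per-model, per-seed metric values into
#' per-model medians, the standard summary used when comparing observation
#' models across simulation repeats.
#'
#' @param results Data frame with columns `model`, `seed`, `metric`, `value`.
#' @param file Optional CSV path to write the aggregated table to.
#' @return Data frame with one row per (model, metric) and columns `median`,
#'   `n_seeds`.
#' @export
comparison_table <- function(results, file = NULL) {
  stopifnot(all(c("model", "seed", "metric", "value") %in% names(results)))
  agg <- stats::aggregate(value ~ model + metric, data = results,
                          FUN = stats::median)
  names(agg)[names(agg) == "value"] <- "median"
  agg$n_seeds <- stats::aggregate(seed ~ model + metric, data = results,
                                  FUN = function(s) length(unique(s)))$seed
  if (!is.null(file)) utils::write.csv(agg, file, row.names = FALSE)
  agg
}
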