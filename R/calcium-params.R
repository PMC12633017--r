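#' Per-neuron calcium observation parameters
#'
#' Bundles the parameters of the spike-to-fluorescence observation model: for
#' each neuron an AR(p) coefficient vector `alpha`, a fluorescence influx per
#' spike `c` (dF/F units), and a Gaussian noise variance `sigma2` (dF/F^2).
#' Under the model a spike raises fluorescence instantaneously by `c`; the AR
#' coefficients govern the subsequent decay (and, for p = 2, the finite rise
#' of the transient); `sigma2` is per-bin process noise.
#'
#' @param alphas Numeric matrix neurons x p of AR coefficients (a vector is
#'   taken as one coefficient per neuron, p = 1).
#' @param c Positive numeric vector, fluorescence influx per spike per neuron.
#' @param sigma2 Positive numeric vector of noise variances per neuron.
#' @return An object of class `calcium_params`.
#' @examples
#' cp <- calcium_params(alphas = c(0.8, 0.9), c = c(1, 1.2), sigma2 = 0.01)
#' cp
#' @export
calcium_params <- function(alphas, c = 1, sigma2 = 0.01) {
  if (is.vector(alphas)) alphas <- matrix(alphas, ncol = 1L)
  alphas <- as.matrix(alphas)
  n <- nrow(alphas)
  c <- rep_len(as.numeric(c), n)
  sigma2 <- rep_len(as.numeric(sigma2), n)
  if (ncol(alphas) < 1L) stop("AR order p must be >= 1")
  if (!all(is.finite(alphas))) stop("AR coefficients must be finite")
  if (any(c <= 0)) stop("influx c must be > 0 for every neuron")
  if (any(sigma2 <= 0)) stop("noise variance sigma2 must be > 0 for every neuron")
  structure(list(alphas = alphas, c = c, sigma2 = sigma2),
            class = "calcium_params")
}

#' @export
print.calcium_params <- function(x, ...) {
  p <- ncol(x$alphas)
  cat(sprintf("<calcium_params> %d neurons, AR(%d)\n", nrow(x$alphas), p))
  cat(sprintf("  alpha: %s\n", summary_line(x$alphas[, 1L])))
  if (p > 1L)
    for (j in 2:p) cat(sprintf("  alpha%d: %s\n", j, summary_line(x$alphas[, j])))
  cat(sprintf("  c    : %s\n", summary_line(x$c)))
  cat(sprintf("  sigma2: %s\n", summary_line(x$sigma2)))
  invisible(x)
}

summary_line <- function(v) {
  if (length(v) == 1L) return(formatC(v, digits = 4, format = "g"))
  sprintf("median %.3g [%.3g, %.3g]", stats::median(v), min(v), max(v))
}

n_neurons <- function(params) nrow(params$alphas)
ar_order <- function(params) ncol(params$alphas)

#' Read/write calcium observation parameters
#'
#' Parameters are serialized as JSON with keys `alphas` (neurons x p),
#' `c` and `sigma2`.
#'
#' @param params A `calcium_params` object.
#' @param path File path.
#' @return `read_calcium_params` returns a `calcium_params`;
#'   `write_calcium_params` returns `path` invisibly.
#' @export
write_calcium_params <- function(params, path) {
  stopifnot(inherits(params, "calcium_params"))
  jsonlite::write_json(
    list(alphas = params$alphas, c = params$c, sigma2 = params$sigma2),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calcium_params
#' @export
read_calcium_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calcium_params(alphas = as.matrix(x$alphas), c = x$c, sigma2 = x$sigma2)
}
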