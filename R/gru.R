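# Minimal batched GRU layer with hand-derived backpropagation-through-time.
# Used by the sequential variational autoencoder (encoder, controller and
# generator networks). Parameters per layer:
#   Wx : I x 3H  input weights, column blocks [reset | update | candidate]
#   Urz: H x 2H  recurrent weights for reset/update gates
#   Un : H x H   recurrent weights for the candidate (applied to r * h)
#   b  : 3H      biases
# Update rule: r = s(ax_r + h Ur), z = s(ax_z + h Uz),
#              n = tanh(ax_n + (r*h) Un), h' = (1 - z)*n + z*h.

gru_params <- function(input_dim, hidden_dim, gain = 1) {
  s <- gain / sqrt(hidden_dim)
  list(Wx = matrix(stats::runif(input_dim * 3 * hidden_dim, -s, s),
                   input_dim, 3 * hidden_dim),
       Urz = matrix(stats::runif(hidden_dim * 2 * hidden_dim, -s, s),
                    hidden_dim, 2 * hidden_dim),
       Un = matrix(stats::runif(hidden_dim * hidden_dim, -s, s),
                   hidden_dim, hidden_dim),
       b = rep(0, 3 * hidden_dim))
}

# X: B x I x T input array; h0: B x H. Returns hidden states B x H x T and
# the caches needed for the backward pass.
gru_forward <- function(par, X, h0) {
  H <- ncol(par$Un)
  B <- dim(X)[1L]; T <- dim(X)[3L]
  hs <- array(0, c(B, H, T))
  cache <- vector("list", T)
  h <- h0
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2 * H + i1
  for (t in seq_len(T)) {
    Xt <- matrix(X[, , t], B)
    ax <- Xt %*% par$Wx + rep(par$b, each = B)
    arz <- ax[, c(i1, i2), drop = FALSE] + h %*% par$Urz
    r <- sigmoid(arz[, i1, drop = FALSE])
    z <- sigmoid(arz[, i2, drop = FALSE])
    an <- ax[, i3, drop = FALSE] + (r * h) %*% par$Un
    n <- tanh(an)
    hprev <- h
    h <- (1 - z) * n + z * hprev
    hs[, , t] <- h
    cache[[t]] <- list(r = r, z = z, n = n, hprev = hprev, Xt = Xt)
  }
  list(h = hs, cache = cache, h_last = h)
}

# dh_seq: B x H x T gradients on each hidden state (may be all-zero);
# dh_last: extra gradient on the final state. Returns parameter gradients,
# input gradients dX (B x I x T) and dh0.
gru_backward <- function(par, cache, dh_seq, dh_last = NULL) {
  T <- length(cache)
  B <- nrow(cache[[1L]]$r); H <- ncol(cache[[1L]]$r)
  I <- nrow(par$Wx)
  g <- list(Wx = par$Wx * 0, Urz = par$Urz * 0, Un = par$Un * 0, b = par$b * 0)
  dX <- array(0, c(B, I, T))
  dh <- if (is.null(dh_last)) matrix(0, B, H) else dh_last
  for (t in rev(seq_len(T))) {
    cc <- cache[[t]]
    dht <- dh + matrix(dh_seq[, , t], B)
    dz <- dht * (cc$hprev - cc$n)
    dn <- dht * (1 - cc$z)
    dh <- dht * cc$z
    dan <- dn * (1 - cc$n^2)
    rh <- cc$r * cc$hprev
    g$Un <- g$Un + crossprod(rh, dan)
    drh <- dan %*% t(par$Un)
    dr <- drh * cc$hprev
    dh <- dh + drh * cc$r
    darz <- cbind(dr * cc$r * (1 - cc$r), dz * cc$z * (1 - cc$z))
    g$Urz <- g$Urz + crossprod(cc$hprev, darz)
    dh <- dh + darz %*% t(par$Urz)
    dax <- cbind(darz, dan)
    g$Wx <- g$Wx + crossprod(cc$Xt, dax)
    g$b <- g$b + colSums(dax)
    dX[, , t] <- dax %*% t(par$Wx)
  }
  list(grads = g, dX = dX, dh0 = dh)
}

# Flatten/unflatten nested parameter lists so one Adam state covers the
# whole model. Names are dot-joined.
flatten_params <- function(nested, prefix = NULL) {
  out <- list()
  for (nm in names(nested)) {
    key <- if (is.null(prefix)) nm else paste0(prefix, ".", nm)
    x <- nested[[nm]]
    if (is.list(x)) out <- c(out, flatten_params(x, key))
    else out[[key]] <- x
  }
  out
}

unflatten_params <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) out[[key]] <- flat[[key]]
    else out[[parts[1L]]][[parts[2L]]] <- flat[[key]]
  }
  out
}
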