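# Differentiable layers kept in R: batch normalization, inverted dropout,
# dense heads, softmax, global average pooling. The convolution/pooling
# kernels live in src/convnet.cpp. All layer functions return the output
# plus whatever the matching *_backward needs.

#' Gaussian error linear unit
#'
#' The exact form `x * pnorm(x)` (standard-normal CDF, not the tanh
#' approximation), used after every convolution in the feature extractor.
#'
#' @param x numeric.
#' @return `x * pnorm(x)`.
#' @export
#' @examples
#' gelu(c(-1, 0, 10))
gelu <- function(x) x * pnorm(x)

gelu_deriv <- function(x) pnorm(x) + x * dnorm(x)

# --- batch normalization (per channel of an (H, W, C, N) tensor) ---------

# internal layout trick: fold (H, W, C, N) to an (H*W*N, C) matrix so all
# per-channel statistics vectorize; .chan_fold/.chan_unfold invert each other
.chan_fold <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

.chan_unfold <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_forward <- function(x, gamma, beta, run_mean, run_var,
                       training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- .chan_fold(x)
  m <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    cen <- xm - rep(mu, each = m)
    v <- colMeans(cen^2)                 # biased variance, as in training BN
    inv <- 1 / sqrt(v + eps)
    xhat <- cen * rep(inv, each = m)
    y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * m / max(m - 1, 1)
    cache <- list(xhat = xhat, inv = inv, m = m, d = d)
  } else {
    inv <- 1 / sqrt(run_var + eps)
    y <- (xm - rep(run_mean, each = m)) * rep(gamma * inv, each = m) +
      rep(beta, each = m)
    cache <- NULL
  }
  list(y = .chan_unfold(y, d), cache = cache,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, gamma, cache) {
  m <- cache$m
  g <- .chan_fold(dy)
  xh <- cache$xhat                       # already folded
  dgamma <- colSums(g * xh)
  dbeta <- colSums(g)
  dxhat <- g * rep(gamma, each = m)
  dx <- (dxhat - rep(colMeans(dxhat), each = m) -
           xh * rep(colMeans(dxhat * xh), each = m)) *
    rep(cache$inv, each = m)
  list(dx = .chan_unfold(dx, cache$d), dgamma = dgamma, dbeta = dbeta)
}

# --- inverted dropout -----------------------------------------------------

dropout_forward <- function(x, keep, training) {
  if (!training || keep >= 1) {
    return(list(y = x, mask = NULL))
  }
  mask <- array((runif(length(x)) < keep) / keep, dim(x))
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# --- global average pooling: (H, W, C, N) -> (C, N) ----------------------

gap_forward <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

gap_backward <- function(dF, in_dim) {
  hw <- in_dim[1] * in_dim[2]
  array(rep(dF / hw, each = hw), in_dim)
}

# --- dense + softmax ------------------------------------------------------

dense_forward <- function(w, b, x) w %*% x + b

dense_backward <- function(w, x, dz) {
  list(dw = dz %*% t(x), db = rowSums(dz), dx = t(w) %*% dz)
}

softmax_cols <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}
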