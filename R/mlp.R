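# Minimal dense feedforward machinery used by the Siamese model.
# All hidden activations are tanh (odd), the output layer is linear.
# Networks are plain lists of weight matrices (and optional bias vectors),
# so the whole model is serialisable and bitwise reproducible.

mlp_init <- function(sizes, bias = TRUE) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- if (bias) vector("list", L) else NULL
  for (l in seq_len(L)) {
    p <- sizes[l]; q <- sizes[l + 1L]
    W[[l]] <- matrix(stats::rnorm(p * q, 0, sqrt(1 / p)), p, q)
    if (bias) b[[l]] <- numeric(q)
  }
  list(W = W, b = b, sizes = sizes, bias = bias)
}

# forward pass; returns output and per-layer activations for backprop
mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% net$W[[l]]
    if (net$bias) Z <- sweep(Z, 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  list(out = A[[L + 1L]], A = A)
}

# backward pass given the gradient of the loss wrt the network output;
# returns parameter gradients and the gradient wrt the input matrix
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- if (net$bias) vector("list", L) else NULL
  delta <- dOut
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    if (net$bias) db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - cache$A[[l]]^2)
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(dW = dW, db = db, dX = delta)
}

# Adam optimiser over an arbitrary nested list of numeric arrays
adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 5e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        if (is.null(p[[i]])) next
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# locale-independent (C collation) string ordering, so seeded draws and
# canonical serialisations do not depend on LC_COLLATE
c_sort <- function(x, ...) sort(x, method = "radix", ...)
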