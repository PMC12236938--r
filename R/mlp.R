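## Minimal fully-connected network with manual backpropagation, Adam updates
## and spectral-norm control. Both neural components of the method -- the
## Lipschitz dual potential (ReLU) and the time-dependent velocity field
## (tanh) -- are small dense nets, so plain BLAS-backed matrix algebra is all
## that is needed; no external deep-learning runtime is involved.

mlp_new <- function(in_dim, hidden, out_dim, activation = c("relu", "tanh"),
                    seed = NULL) {
  activation <- match.arg(activation)
  if (!is.null(seed)) set.seed(seed)
  sizes <- c(in_dim, hidden, out_dim)
  nl <- length(sizes) - 1L
  W <- vector("list", nl)
  b <- vector("list", nl)
  u <- vector("list", nl)  # persistent power-iteration vectors
  for (l in seq_len(nl)) {
    fan_in <- sizes[l]
    sd <- if (activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sd),
                     nrow = sizes[l], ncol = sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
    u[[l]] <- stats::rnorm(sizes[l + 1L])
    u[[l]] <- u[[l]] / sqrt(sum(u[[l]]^2))
  }
  structure(list(W = W, b = b, u = u, sizes = sizes, activation = activation),
            class = "profet_mlp")
}

mlp_n_layers <- function(net) length(net$W)

.act <- function(Z, kind) if (kind == "relu") pmax(Z, 0) else tanh(Z)
.act_grad <- function(Z, A, kind) {
  if (kind == "relu") (Z > 0) + 0 else 1 - A^2
}

# Forward pass; keeps activations for backprop.
mlp_forward <- function(net, X) {
  X <- as.matrix(X)
  nl <- mlp_n_layers(net)
  H <- vector("list", nl + 1L)
  Z <- vector("list", nl)
  H[[1L]] <- X
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(H[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    H[[l + 1L]] <- if (l < nl) .act(Z[[l]], net$activation) else Z[[l]]
  }
  list(out = H[[nl + 1L]], H = H, Z = Z)
}

mlp_predict <- function(net, X) mlp_forward(net, X)$out

# Backpropagate dL/d(out) through the cached forward pass. Returns parameter
# gradients and the gradient with respect to the input rows.
mlp_backprop <- function(net, fwd, dout) {
  nl <- mlp_n_layers(net)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  dZ <- as.matrix(dout)
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(fwd$H[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dH <- tcrossprod(dZ, net$W[[l]])
    if (l > 1L) dZ <- dH * .act_grad(fwd$Z[[l - 1L]], fwd$H[[l]], net$activation)
  }
  list(gW = gW, gb = gb, dX = dH)
}

# Gradient of a scalar-output network with respect to its input, one row per
# sample (automatic differentiation by reverse accumulation).
mlp_input_grad <- function(net, X) {
  fwd <- mlp_forward(net, X)
  if (ncol(fwd$out) != 1L)
    stop("input gradient is defined for scalar-output networks")
  mlp_backprop(net, fwd, matrix(1, nrow(fwd$out), 1L))$dX
}

## ---- Adam optimiser ----

adam_init <- function(net) {
  zW <- lapply(net$W, function(w) array(0, dim(w)))
  zb <- lapply(net$b, function(v) numeric(length(v)))
  list(mW = zW, vW = zW, mb = zb, vb = zb, t = 0L)
}

adam_step <- function(net, state, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, maximize = FALSE) {
  sgn <- if (maximize) -1 else 1
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    gw <- sgn * grads$gW[[l]]
    gb <- sgn * grads$gb[[l]]
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * gw
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * gw^2
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * gb
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * gb^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

## ---- Spectral-norm control ----

# Estimate the spectral norm of W by power iteration, reusing (and updating)
# the persistent right-singular-vector estimate u.
.power_sigma <- function(W, u, iters = 5L) {
  for (i in seq_len(iters)) {
    v <- as.vector(W %*% u)
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(list(sigma = 0, u = u))
    v <- v / nv
    u <- as.vector(crossprod(W, v))
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(list(sigma = 0, u = u))
    u <- u / nu
  }
  list(sigma = sqrt(sum((W %*% u)^2)), u = u)
}

# Project every layer so its spectral norm is at most `cap`. With 1-Lipschitz
# activations this bounds the whole network's Lipschitz constant by
# cap^(number of weight layers). `exact = TRUE` uses an SVD-based norm so the
# bound holds to machine precision (used before velocities are emitted).
mlp_spectral_project <- function(net, cap, exact = FALSE, power_iters = 5L) {
  for (l in seq_along(net$W)) {
    if (exact) {
      sigma <- norm(net$W[[l]], type = "2")
    } else {
      ps <- .power_sigma(net$W[[l]], net$u[[l]], power_iters)
      sigma <- ps$sigma
      net$u[[l]] <- ps$u
    }
    if (sigma > cap) net$W[[l]] <- net$W[[l]] * (cap / sigma)
  }
  net
}

# Product of exact per-layer spectral norms: an upper bound on the network's
# global Lipschitz constant (activations are 1-Lipschitz).
mlp_lipschitz_bound <- function(net) {
  prod(vapply(net$W, function(w) norm(w, type = "2"), numeric(1)))
}
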