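# Small deterministic builders shared across the test files.

# two-gene toy network: gene 1 inhibits gene 2
toy_grn <- function(D = 0) {
  J <- matrix(c(0L, 0L,
                -1L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  lam <- matrix(1, 2, 2); lam[2, 1] <- 0.2
  theta <- matrix(1, 2, 2); theta[2, 1] <- 3
  n <- matrix(1, 2, 2); n[2, 1] <- 2
  grn_model(J, g = c(2, 4), k = c(1, 0.5), lam = lam, theta = theta, n = n,
            D = D)
}

# unregulated model: J all zero
free_grn <- function(G = 3, g = NULL, k = NULL, D = 0) {
  J <- matrix(0L, G, G)
  if (is.null(g)) g <- seq_len(G) + 1
  if (is.null(k)) k <- rep(0.5, G)
  one <- matrix(1, G, G)
  grn_model(J, g = g, k = k, lam = one, theta = one, n = one, D = D)
}

# snapshot series of 1-D Gaussians at the given means
gaussian_series <- function(means, times = seq_along(means) - 1, n = 100,
                            sd = 1, seed = 1) {
  set.seed(seed)
  mats <- lapply(means, function(mu)
    matrix(rnorm(n, mu, sd), ncol = 1, dimnames = list(NULL, "g1")))
  snapshot_series(mats, times = times)
}

# constant-output scalar network (all weights zero, output bias = value)
constant_potential <- function(value, d = 1) {
  net <- profet:::mlp_new(d, c(8, 8), 1L, activation = "relu", seed = 1)
  for (l in seq_along(net$W)) net$W[[l]][] <- 0
  net$b[[length(net$b)]][] <- value
  net
}

# brute-force maximizer of the 1-D variational KL objective over discretized
# L-Lipschitz potentials: phi is parameterized by an offset and bounded
# increments on a shared grid, maximized by projected gradient ascent
lipschitz_kl_oracle <- function(y, x, L = 1, n_grid = 201L, iters = 4000L,
                                lr = 0.05) {
  rng <- range(c(y, x))
  grid <- seq(rng[1] - 0.5, rng[2] + 0.5, length.out = n_grid)
  dx <- diff(grid)[1]
  iy <- findInterval(y, grid, all.inside = TRUE)
  ix <- findInterval(x, grid, all.inside = TRUE)
  a <- 0
  u <- rep(0, n_grid - 1L)  # increments, |u| <= L * dx
  phi_at <- function(a, u, idx) (a + c(0, cumsum(u)))[idx]
  for (it in seq_len(iters)) {
    phi_y <- phi_at(a, u, iy)
    phi_x <- phi_at(a, u, ix)
    w_x <- exp(phi_x - 1) / length(x)
    # gradient wrt phi values: +1/N at y-points, -w at x-points
    gv <- rep(0, n_grid)
    tab_y <- tabulate(iy, n_grid) / length(y)
    gv <- gv + tab_y
    for (k in seq_along(ix)) gv[ix[k]] <- gv[ix[k]] - w_x[k]
    a <- a + lr * sum(gv)
    # d/d u_j = sum of gv over grid points above j
    gu <- rev(cumsum(rev(gv)))[-1]
    u <- pmin(pmax(u + lr * gu, -L * dx), L * dx)
  }
  mean(phi_at(a, u, iy)) - mean(exp(phi_at(a, u, ix) - 1))
}

# compact GPA settings for unit-test-scale runs (overridable)
test_gpa_config <- function(...) {
  defaults <- list(hidden = c(32L, 32L, 32L), inner_iters = 25L,
                   inner_iters_init = 250L, max_iters = 80L)
  do.call(gpa_config, utils::modifyList(defaults, list(...)))
}

test_fm_config <- function(...) {
  defaults <- list(hidden = c(32L, 32L, 32L, 32L), epochs = 1200L)
  do.call(fm_config, utils::modifyList(defaults, list(...)))
}
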