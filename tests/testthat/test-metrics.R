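eps_grid <- c(0.01, 0.1, 1, 10, 100)

test_that("entropic OT cost has its closed form on atoms", {
  x <- matrix(0); y <- matrix(2.5)
  for (eps in eps_grid) {
    # forced coupling gamma = 1: cost r^2 + eps(log 1 - 1)
    expect_equal(entropic_ot_cost(x, y, eps), 2.5^2 - eps, tolerance = 1e-9)
    expect_equal(entropic_ot_cost(x, x, eps), -eps, tolerance = 1e-9)
  }
  expect_error(entropic_ot_cost(x, y, 0), "epsilon")
})

test_that("large epsilon drives the cost to the independent coupling value", {
  set.seed(30)
  X <- matrix(rnorm(30), ncol = 1)
  Y <- matrix(rnorm(40, 2), ncol = 1)
  # evaluate the regularized objective at gamma = a (x) b
  C <- outer(X[, 1], Y[, 1], function(a, b) (a - b)^2)
  a <- rep(1 / 30, 30); b <- rep(1 / 40, 40)
  G <- a %o% b
  indep <- sum(G * C) + 1e6 * sum(G * (log(G) - 1))
  expect_equal(entropic_ot_cost(X, Y, 1e6), indep, tolerance = 1e-6 * abs(indep))
})

test_that("Sinkhorn divergence is debiased, symmetric and exact on atoms", {
  set.seed(31)
  X <- matrix(rnorm(50, 0, 0.5), ncol = 1)
  for (eps in eps_grid)
    expect_equal(sinkhorn_divergence(matrix(0), matrix(1.7), eps), 1.7^2,
                 tolerance = 1e-8)
  expect_equal(sinkhorn_divergence(X, X, 0.1), 0, tolerance = 1e-8)
  Y <- matrix(rnorm(40, 1, 0.5), ncol = 1)
  expect_equal(sinkhorn_divergence(X, Y, 1, tol = 1e-12, max_iter = 50000L),
               sinkhorn_divergence(Y, X, 1, tol = 1e-12, max_iter = 50000L),
               tolerance = 1e-10)
  expect_gte(sinkhorn_divergence(X, Y, 1), -1e-8)
})

test_that("Sinkhorn divergence grows with cloud separation", {
  set.seed(32)
  base <- matrix(rnorm(60), ncol = 1)
  vals <- vapply(c(0.5, 1, 2, 4), function(sh)
    sinkhorn_divergence(base, base + sh, 1), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("squared MMD matches closed forms and a brute-force double loop", {
  expect_equal(mmd_rbf(matrix(0), matrix(1.3)), 2 - 2 * exp(-1.3^2))
  set.seed(33)
  X <- matrix(rnorm(30), ncol = 1)
  expect_equal(mmd_rbf(X, X), 0)
  brute <- function(X, Y, g) {
    s <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X)))
      s <- s + exp(-g * sum((X[i, ] - X[j, ])^2))
    s <- s / nrow(X)^2
    t2 <- 0
    for (i in seq_len(nrow(Y))) for (j in seq_len(nrow(Y)))
      t2 <- t2 + exp(-g * sum((Y[i, ] - Y[j, ])^2))
    s <- s + t2 / nrow(Y)^2
    cr <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y)))
      cr <- cr + exp(-g * sum((X[i, ] - Y[j, ])^2))
    s - 2 * cr / (nrow(X) * nrow(Y))
  }
  for (rep in 1:10) {
    Xr <- matrix(rnorm(40), 20, 2)
    Yr <- matrix(rnorm(40, 0.5), 20, 2)
    expect_equal(mmd_rbf(Xr, Yr, gamma = 1), brute(Xr, Yr, 1),
                 tolerance = 1e-10)
  }
  expect_error(mmd_rbf(X[0, , drop = FALSE], X), "empty")
})

test_that("histogram TV and KL behave on known distributions", {
  set.seed(34)
  a <- rnorm(100)
  expect_equal(tv_distance(a, a), 0)
  expect_equal(kl_estimate(a, a), 0)
  expect_equal(tv_distance(rep(1, 50), rep(1, 50)), 0)  # degenerate pool
  # disjoint supports
  expect_equal(tv_distance(runif(60), runif(60) + 10), 1)
  # hand-built histograms p = (.5, .5), q = (.25, .75) -> TV 0.25
  a2 <- c(rep(0.25, 2), rep(0.75, 2))
  b2 <- c(0.25, rep(0.75, 3))
  expect_equal(tv_distance(a2, b2, bins = 2), 0.25)
  expect_equal(kl_estimate(a2, b2, bins = 2),
               0.5 * log(0.5 / 0.25) + 0.5 * log(0.5 / 0.75),
               tolerance = 1e-6)
})

test_that("metrics are invariant to point order", {
  set.seed(35)
  X <- matrix(rnorm(40), 20, 2)
  Y <- matrix(rnorm(40, 1), 20, 2)
  p <- sample(20)
  expect_equal(sinkhorn_divergence(X, Y, 1), sinkhorn_divergence(X[p, ], Y, 1),
               tolerance = 1e-9)
  expect_equal(mmd_rbf(X, Y), mmd_rbf(X[p, ], Y[p, ]))
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(tv_distance(a, b), tv_distance(sample(a), b))
})

test_that("coupling interpolants hit their endpoints and midpoints", {
  set.seed(36)
  src <- matrix(rnorm(30), ncol = 1)
  tgt <- matrix(rnorm(30, 4), ncol = 1)
  i0 <- ot_coupling_interpolate(src, tgt, 0)
  expect_setequal(round(unique(i0$points[, 1]), 9), round(src[, 1], 9))
  i1 <- ot_coupling_interpolate(src, tgt, 1)
  expect_setequal(round(unique(i1$points[, 1]), 9), round(tgt[, 1], 9))
  # two single atoms: midpoint
  mid <- ot_coupling_interpolate(matrix(0), matrix(2), 0.5)
  expect_equal(mid$points[1, 1], 1)
  mid_r <- random_coupling_interpolate(matrix(0), matrix(2), 0.5)
  expect_equal(mid_r$points[1, 1], 1)
  r0 <- random_coupling_interpolate(src, tgt, 0, seed = 2)
  expect_equal(r0$points, src, ignore_attr = TRUE)
  expect_error(ot_coupling_interpolate(src, tgt, 1.2), "t_frac")
  # determinism of the seeded pairing
  expect_identical(random_coupling_interpolate(src, tgt, 0.3, seed = 4),
                   random_coupling_interpolate(src, tgt, 0.3, seed = 4))
})

test_that("evaluation report covers every method and epsilon", {
  set.seed(37)
  preds <- list(profet = matrix(rnorm(20)), baseline = matrix(rnorm(20, 1)))
  obs <- matrix(rnorm(20))
  rep_ <- evaluation_report(preds, obs, eps_grid = c(0.1, 1), gamma = 1,
                            time = 2)
  expect_equal(nrow(rep_), 2 * (2 + 1))
  expect_setequal(unique(rep_$method), c("profet", "baseline"))
  expect_true(all(rep_$value[rep_$metric == "mmd"] >= 0))
})
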