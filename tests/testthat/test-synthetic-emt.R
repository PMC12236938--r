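test_that("shifted Hill function matches its closed form and bounds", {
  expect_equal(shifted_hill(0, lam = 5, theta = 10, n = 2), 1)
  expect_equal(shifted_hill(0, lam = 0.2, theta = 1, n = 4), 1)
  expect_equal(shifted_hill(10, lam = 5, theta = 10, n = 2), (1 + 5) / 2)
  expect_equal(shifted_hill(3, lam = 1, theta = 0.5, n = 3), 1)
  expect_error(shifted_hill(1, 2, theta = -1, n = 1), "theta")
  expect_error(shifted_hill(1, 2, theta = 1, n = 0), "n must")
  # bounded by [min(1, lam), max(1, lam)] over a random grid
  set.seed(4)
  for (i in 1:50) {
    lam <- exp(runif(1, -2, 2)); x <- runif(1, 0, 50)
    hs <- shifted_hill(x, lam, theta = runif(1, 0.1, 10), n = sample(1:6, 1))
    expect_gte(hs, min(1, lam) - 1e-12)
    expect_lte(hs, max(1, lam) + 1e-12)
  }
})

test_that("drift has the stated fixed points and regulator limits", {
  m0 <- free_grn()
  expect_equal(grn_drift(m0$g / m0$k, m0), rep(0, 3))
  expect_equal(grn_drift(rep(0, 3), m0), m0$g)
  expect_error(grn_drift(rep(1, 4), m0), "dimension")
  # single inhibitor saturates to g * lam - k * x
  m <- toy_grn()
  x <- c(1e6 * m$theta[2, 1], 2)
  expected <- m$g[2] * m$lam[2, 1] - m$k[2] * x[2]
  expect_equal(grn_drift(x, m)[2], expected, tolerance = 1e-3)
  # row-wise matrix evaluation agrees with vector evaluation
  X <- rbind(c(1, 2), c(4, 0.5))
  expect_equal(grn_drift(X, m)[1, ], grn_drift(X[1, ], m))
})

test_that("Euler-Maruyama integration is reproducible and consistent", {
  m <- toy_grn(D = 0.3)
  tr0 <- simulate_grn(m, c(1, 1), dt = 0.01, t_end = 0, seed = 5)
  expect_equal(dim(tr0$values), c(1L, 1L, 2L))
  expect_equal(drop(tr0$values[1, 1, ]), c(a = 1, b = 1))
  tr1 <- simulate_grn(m, c(1, 1), dt = 0.01, t_end = 2, seed = 5)
  tr2 <- simulate_grn(m, c(1, 1), dt = 0.01, t_end = 2, seed = 5)
  expect_identical(tr1$values, tr2$values)
  expect_error(simulate_grn(m, c(1, 1), dt = -0.1, t_end = 1), "dt")
})

test_that("deterministic limit agrees with a 10x finer Euler integration", {
  m <- toy_grn(D = 0)
  coarse <- simulate_grn(m, c(0.5, 6), dt = 0.02, t_end = 3, seed = 1)
  fine <- simulate_grn(m, c(0.5, 6), dt = 0.002, t_end = 3, seed = 1)
  end_c <- coarse$values[1, dim(coarse$values)[2], ]
  end_f <- fine$values[1, dim(fine$values)[2], ]
  # global error of forward Euler is O(dt)
  expect_lt(max(abs(end_c - end_f)), 10 * 0.02)
})

test_that("unregulated dynamics converge to g/k from any start", {
  m <- free_grn(G = 4, g = c(2, 5, 9, 1), k = c(0.6, 1, 2, 0.5), D = 0)
  set.seed(2)
  x0 <- runif(4, 0, 20)
  tr <- simulate_grn(m, x0, dt = 0.005, t_end = 20 / min(m$k), seed = 1)
  terminal <- tr$values[1, dim(tr$values)[2], ]
  expect_equal(unname(terminal), m$g / m$k, tolerance = 1e-6)
})

test_that("with noise, the replicate mean tracks the deterministic solution", {
  m <- toy_grn(D = 0.2)
  det <- simulate_grn(toy_grn(D = 0), c(1, 1), dt = 0.01, t_end = 0.5, seed = 1)
  sto <- simulate_grn(m, c(1, 1), dt = 0.01, t_end = 0.5, seed = 3, n_rep = 600)
  last <- dim(sto$values)[2]
  for (gidx in 1:2) {
    mu <- mean(sto$values[, last, gidx])
    se <- sd(sto$values[, last, gidx]) / sqrt(600)
    expect_lt(abs(mu - det$values[1, last, gidx]), 3 * se + 1e-8)
  }
})

test_that("parameter ensembles respect ranges and edge-sign constraints", {
  J <- matrix(c(0L, 1L, -1L, 0L), 2, 2, byrow = TRUE)
  # degenerate ranges pin the model down completely
  rng <- list(g = c(2, 2), k = c(0.5, 0.5), lam_act = c(3, 3),
              lam_inh = c(0.2, 0.2), theta_frac = c(1, 1), n = c(2, 2))
  mods <- sample_grn_ensemble(J, 1, ranges = rng, seed = 9)
  expect_length(mods, 1L)
  expect_equal(mods[[1]]$g, c(2, 2))
  expect_equal(mods[[1]]$lam[1, 2], 3)
  expect_equal(mods[[1]]$lam[2, 1], 0.2)
  expect_equal(mods[[1]]$theta[1, 2], 2 / 0.5)
  bad <- rng; bad$g <- c(5, 1)
  expect_error(sample_grn_ensemble(J, 1, ranges = bad), "inverted")
  # default ranges: activation lam > 1, inhibition lam in (0, 1)
  mods <- sample_grn_ensemble(J, 50, seed = 11)
  for (m in mods) {
    expect_gt(m$lam[1, 2], 1)
    expect_gt(m$lam[2, 1], 0); expect_lt(m$lam[2, 1], 1)
  }
  # production-rate marginal is uniform on its range (KS test, alpha = 0.01)
  g_draws <- unlist(lapply(sample_grn_ensemble(J, 100, seed = 13),
                           function(m) m$g))
  ks <- suppressWarnings(ks.test(g_draws, "punif", 1, 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("snapshot subsampling uses nearest grid points with earlier ties", {
  m <- toy_grn(D = 0.1)
  tr <- simulate_grn(m, c(1, 2), dt = 0.1, t_end = 1, seed = 2, n_rep = 5)
  # full grid round-trips all values
  full <- subsample_snapshots(tr, tr$times)
  for (i in seq_along(tr$times))
    expect_equal(unname(full$matrices[[i]]), unname(tr$values[, i, ]))
  # 0.25 is equidistant between grid points 0.2 and 0.3 -> earlier wins
  s <- subsample_snapshots(tr, 0.25)
  expect_equal(unname(s$matrices[[1]]), unname(tr$values[, 3, ]))
  expect_error(subsample_snapshots(tr, 2), "outside")
})

test_that("the packaged EMT topology loads and simulates at scale", {
  J <- read_grn_topology(system.file("extdata", "emt_grn_26_synthetic.txt",
                                     package = "profet"))
  expect_equal(dim(J), c(26L, 26L))
  expect_true(all(J %in% c(-1L, 0L, 1L)))
  series <- simulate_emt_series(n_rep = 40, sample_times = 0:4, seed = 2)
  expect_length(series$matrices, 5L)
  expect_equal(dim(series$matrices[[1]]), c(40L, 26L))
  expect_true(all(vapply(series$matrices, function(m) all(m >= 0), TRUE)))
  # reproducibility
  series2 <- simulate_emt_series(n_rep = 40, sample_times = 0:4, seed = 2)
  expect_identical(series$matrices, series2$matrices)
})
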