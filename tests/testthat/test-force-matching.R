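# helper: velocity sample table in the shape emitted by run_gpa/align_times
vel_samples <- function(x, v, s, subinterval = 1L) {
  data.frame(x1 = x, t_local = 0, v1 = v, iter = 0L,
             subinterval = subinterval, s = s)
}

test_that("time alignment maps local clocks affinely onto observation intervals", {
  rec <- data.frame(x1 = rep(0, 3), t_local = c(0, 5, 10), v1 = c(1, 1, 1),
                    iter = 0:2, subinterval = 1L)
  out <- align_times(rec, observation_times = c(0, 4), horizons = 10)
  expect_equal(out$s, c(0, 2, 4))
  # chain rule: ds/dt = 4/10, so velocities grow by 10/4
  expect_equal(out$v1, rep(10 / 4, 3))
  # inverse map recovers local times
  expect_equal((out$s - 0) * 10 / 4, rec$t_local, tolerance = 1e-10)

  # two subintervals with different horizons stay in their own windows
  rec2 <- rbind(rec, transform(rec, t_local = c(0, 2, 4), subinterval = 2L))
  out2 <- align_times(rec2, observation_times = c(0, 2, 4),
                      horizons = c(10, 4))
  expect_equal(out2$s[out2$subinterval == 1], c(0, 1, 2))
  expect_equal(out2$s[out2$subinterval == 2], c(2, 3, 4))
  expect_error(align_times(transform(rec, subinterval = 3L),
                           observation_times = c(0, 2, 4),
                           horizons = c(1, 1)), "unknown subinterval")

  # longest-horizon mode: one shared dilation factor
  outl <- align_times(rec2, observation_times = c(0, 2, 4),
                      horizons = c(10, 4), mode = "longest-horizon")
  expect_equal(outl$s[outl$subinterval == 2], 2 + c(0, 2, 4) * (2 / 10))
})

test_that("force-matching loss is the mean squared velocity deviation", {
  sm <- vel_samples(x = c(0, 1, 2), v = c(1, 2, 0), s = c(0, 0.5, 1))
  exact <- function(X, s) matrix(c(1, 2, 0)[match(X[, 1], c(0, 1, 2))])
  expect_equal(force_matching_loss(exact, sm), 0)
  off <- function(X, s) exact(X, s) + 0.7
  expect_equal(force_matching_loss(off, sm), 0.7^2)
  # 3-sample hand arithmetic: predictions (0.5, 2.5, -1)
  f3 <- function(X, s) matrix(c(0.5, 2.5, -1)[match(X[, 1], c(0, 1, 2))])
  expect_equal(force_matching_loss(f3, sm),
               (0.5^2 + 0.5^2 + 1^2) / 3)
  expect_error(force_matching_loss(exact, sm[0, ]), "empty")
})

test_that("training recovers a constant velocity field", {
  set.seed(20)
  n <- 600
  sm <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2),
                   t_local = 0, v1 = 1, v2 = 0, iter = 0L,
                   subinterval = 1L, s = runif(n))
  field <- train_velocity_field(sm, test_fm_config(seed = 21))
  grid <- as.matrix(expand.grid(seq(-1.5, 1.5, 0.5), seq(-1.5, 1.5, 0.5)))
  pred <- predict_velocity(field, grid, 0.5)
  expect_lt(max(abs(pred[, 1] - 1)), 0.05)
  expect_lt(max(abs(pred[, 2] - 0)), 0.05)
})

test_that("training recovers a linear decay field within 10%", {
  set.seed(22)
  x <- runif(1500, -2, 2)
  sm <- vel_samples(x = x, v = -x, s = runif(1500))
  field <- train_velocity_field(sm, test_fm_config(seed = 23))
  grid <- matrix(seq(-1.8, 1.8, length.out = 37), ncol = 1)
  pred <- predict_velocity(field, grid, 0.5)
  rel <- sqrt(mean((pred + grid)^2)) / sqrt(mean(grid^2))
  expect_lt(rel, 0.1)
  # reproducibility of trained weights
  field2 <- train_velocity_field(sm, test_fm_config(seed = 23))
  expect_identical(field$network$W, field2$network$W)
})

test_that("Euler integration matches closed forms on simple fields", {
  zero <- function(X, s) X * 0
  x0 <- matrix(c(-1, 0, 2), ncol = 1)
  tr <- integrate_trajectories(zero, x0, 0, 1, 50)
  expect_equal(states_at(tr, 1), x0)
  cfield <- function(X, s) matrix(2, nrow(X), 1)
  tr <- integrate_trajectories(cfield, x0, 0, 0.5, 7)
  expect_equal(states_at(tr, 0.5), x0 + 2 * 0.5)  # exact for constant fields
  decay <- function(X, s) -X
  tr <- integrate_trajectories(decay, matrix(1), 0, 1, 1000)
  expect_equal(states_at(tr, 1)[1, 1], exp(-1), tolerance = 2e-3)
  expect_error(integrate_trajectories(zero, x0, 0, 1, 0), "n_steps")
})

test_that("halving the Euler step changes endpoints at first order", {
  decay <- function(X, s) -X
  e1 <- states_at(integrate_trajectories(decay, matrix(1), 0, 1, 100), 1)
  e2 <- states_at(integrate_trajectories(decay, matrix(1), 0, 1, 200), 1)
  # both within the O(h) bound, and refinement moves toward the truth
  expect_lt(abs(e1 - exp(-1)), exp(-1) * 1 / 100)
  expect_lt(abs(e2 - exp(-1)), abs(e1 - exp(-1)))
})

test_that("three-snapshot toy captures the mid-course turning point", {
  # N(0,1) -> N(3,1) -> N(0,1): trained on both subintervals, the
  # reconstructed flow must rise toward 3 at the middle time, which a
  # straight source-to-final interpolation cannot do
  set.seed(24)
  a <- matrix(rnorm(150), ncol = 1)
  b <- matrix(rnorm(150, 3), ncol = 1)
  c2 <- matrix(rnorm(150), ncol = 1)
  g1 <- run_gpa(a, b, test_gpa_config(seed = 25, max_iters = 100L),
                subinterval_id = 1L)
  g2 <- run_gpa(b, c2, test_gpa_config(seed = 26, max_iters = 100L),
                subinterval_id = 2L)
  sm <- align_times(list(g1, g2), c(0, 1, 2))
  field <- train_velocity_field(sm, test_fm_config(seed = 27))
  tr <- integrate_trajectories(field, a, 0, 2, 400)
  expect_gt(mean(states_at(tr, 1)), 2)
  # endpoints return toward 0
  expect_lt(abs(mean(states_at(tr, 2))), 0.8)
  # linear source-to-final interpolation misses the excursion entirely
  lin <- random_coupling_interpolate(a, c2, 0.5, seed = 28)
  expect_lt(abs(mean(lin$points)), 0.5)
})
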