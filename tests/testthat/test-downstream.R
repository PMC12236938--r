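test_that("permutation test handles identical and separated samples", {
  x <- c(1, 2, 3, 4, 5)
  r <- permutation_test(x, x, metric = "tv", n_perm = 99, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)
  # complete separation: the observed split is (near) maximal
  a <- rep(0, 10) + rnorm(10, sd = 0.01)
  b <- rep(10, 10) + rnorm(10, sd = 0.01)
  r2 <- permutation_test(a, b, metric = "tv", n_perm = 1000, seed = 2)
  expect_lte(r2$p_value, 0.01)
  r3 <- permutation_test(a, b, metric = "sinkhorn", n_perm = 200, seed = 3)
  expect_lte(r3$p_value, 0.01)
  expect_error(permutation_test(a, b, n_perm = 0), "n_perm")
  # p can never be exactly zero and never exceeds 1
  expect_gte(r3$p_value, 1 / 201)
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(5)
  rej <- vapply(1:200, function(i) {
    a <- rnorm(40); b <- rnorm(40)
    permutation_test(a, b, metric = "tv", n_perm = 99, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.045)
})

test_that("fate classification picks k by silhouette and assigns nearest centroids", {
  set.seed(6)
  ref <- rbind(matrix(rnorm(100, 0, 0.5), ncol = 2),
               matrix(rnorm(100, 10, 0.5), ncol = 2))
  pred <- rbind(c(0.2, -0.1), c(9.8, 10.1), c(0, 0.3))
  cl <- classify_fates(ref, pred, k_candidates = 2:5, seed = 7)
  expect_equal(cl$k, 2L)
  expect_equal(cl$labels[1], cl$labels[3])
  expect_false(cl$labels[1] == cl$labels[2])
  # a predicted point exactly at a centroid belongs to that cluster: the two
  # centroids land in two different clusters, consistent with the blob labels
  at_centroid <- classify_fates(ref, cl$centers, k_candidates = 2:3, seed = 7)
  expect_equal(sort(unique(at_centroid$labels)), 1:2)
  # equidistant point -> lowest-index centroid
  ref1 <- rbind(matrix(c(-1, 0), 1), matrix(c(1, 0), 1))
  cl2 <- list(centers = ref1)
  D <- profet:::cpp_sqdist(matrix(c(0, 0), 1), ref1)
  expect_equal(which.min(D[1, ]), 1L)
  expect_error(classify_fates(ref[1:3, ], pred, k_candidates = 2:8),
               "fewer reference points")
})

test_that("fate partitions agree across seeds on well-separated data", {
  set.seed(8)
  ref <- rbind(matrix(rnorm(60, 0, 0.4), ncol = 2),
               matrix(rnorm(60, 8, 0.4), ncol = 2),
               matrix(rnorm(60, c(16, 0), 0.4), ncol = 2))
  pred <- ref + rnorm(length(ref), sd = 0.1)
  l1 <- classify_fates(ref, pred, seed = 1)$labels
  l2 <- classify_fates(ref, pred, seed = 99)$labels
  # same partition up to label permutation
  expect_equal(length(unique(paste(l1, l2))), length(unique(l1)))
})

test_that("displacement stratification recovers a trimodal mixture", {
  set.seed(9)
  comp <- rep(1:3, each = 200)
  disp <- rnorm(600, mean = c(1, 5, 9)[comp], sd = 0.3)
  tab <- data.frame(x_pre = 0, x_post = disp)
  tr <- trajectories_from_endpoints(tab)
  st <- stratify_by_displacement(tr, 0, 1)
  expect_length(st$cutoffs, 2L)
  expect_gt(st$cutoffs[1], 2); expect_lt(st$cutoffs[1], 4)
  expect_gt(st$cutoffs[2], 6); expect_lt(st$cutoffs[2], 8)
  expect_gte(mean(st$group == comp), 0.9)
  sizes <- table(st$group)
  expect_true(all(abs(sizes - 200) <= 40))
})

test_that("stratification summary statistics and degenerate cases", {
  # hand-built 4-value example
  tab <- data.frame(x_pre = 0, x_post = c(1, 2, 3, 6))
  tr <- trajectories_from_endpoints(tab)
  st <- suppressWarnings(stratify_by_displacement(tr, 0, 1))
  expect_equal(unname(st$summary["mean"]), 3)
  expect_equal(unname(st$summary["cv"]), sd(c(1, 2, 3, 6)) / 3)
  expect_equal(unname(st$summary["iqr"]), IQR(c(1, 2, 3, 6)))
  # all-stationary trajectories: one group, CV reported as 0
  tab0 <- data.frame(x_pre = 1, x_post = 1)
  tr0 <- trajectories_from_endpoints(tab0[rep(1, 10), ])
  st0 <- stratify_by_displacement(tr0, 0, 1)
  expect_equal(unique(st0$group), 1L)
  expect_equal(unname(st0$summary["cv"]), 0)
  expect_error(stratify_by_displacement(tr0, 1, 0), "earlier")
})

test_that("normalized divergence profiles are scaled, timed and flagged", {
  times <- seq(0, 4, by = 0.5)
  m2 <- rep(0, length(times))
  # identical groups: all-zero profile, degenerate flag
  nd0 <- normalized_divergence(m2, m2, times)
  expect_true(nd0$degenerate)
  expect_equal(nd0$profile, rep(0, length(times)))
  expect_false(nd0$divergent)
  # linear ramp crosses 0.5 at t = 2
  ramp <- times
  nd <- normalized_divergence(ramp, m2, times)
  expect_equal(max(abs(nd$profile)), 1)
  expect_equal(nd$profile[length(times)], 1)
  expect_true(nd$divergent)
  expect_equal(nd$t_divergence, 2)
  # scale invariance
  nd_s <- normalized_divergence(5 * ramp, 5 * m2, times)
  expect_equal(nd_s$profile, nd$profile)
  # convergence: a profile that rises then collapses
  prof <- c(0, 2, 4, 4, 0.5, 0.2, 0.1, 0, 0)
  ndc <- normalized_divergence(prof, rep(0, 9), times[1:9])
  expect_true(ndc$convergent)
  expect_equal(ndc$t_convergence, times[5])
})

test_that("differential expression gives exact fold changes and t-tests", {
  a <- cbind(g1 = c(1, 2, 3), g2 = c(2, 2, 2))
  b <- cbind(g1 = c(4, 5, 6), g2 = c(1, 1.5, 0.5))
  res <- deg_analysis(a, b)
  # printed 3-value vectors: equal variances, so Welch reduces to pooled t
  expect_equal(res$log2fc[1], log2(2 / 5), tolerance = 1e-6)
  tt <- t.test(a[, "g1"], b[, "g1"])
  expect_equal(tt$statistic[["t"]], -3.674, tolerance = 1e-3)
  expect_equal(res$p[1], 0.0213, tolerance = 1e-2)
  expect_equal(res$p[1], tt$p.value)
  # mean_a = 2 * mean_b -> log2FC = 1
  expect_equal(res$log2fc[2], 1, tolerance = 1e-6)
  # equal means -> log2FC 0; zero variance in both -> p = 1
  z <- cbind(g1 = c(3, 3))
  res0 <- deg_analysis(rbind(z, z), rbind(z, z))
  expect_equal(res0$log2fc, 0)
  expect_equal(res0$p, 1)
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
  expect_error(deg_analysis(a[1, , drop = FALSE], b), "at least 2")
})
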