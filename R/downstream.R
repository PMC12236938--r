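## Statistical interpretation of reconstructed trajectories: permutation
## tests against held-out data, fate/origin classification, displacement
## stratification, divergence/convergence timing, and trajectory-aware
## differential expression.

#' Permutation test of predicted versus observed 1-D distributions
#'
#' Tests the null that both samples come from the same distribution: pools
#' them, reshuffles the labels `n_perm` times into groups of the original
#' sizes, and reports the one-sided p-value with the add-one correction
#' \eqn{p = (\#\{d_{perm} \ge d_{obs}\} + 1) / (n_{perm} + 1)}, so p is never
#' exactly zero.
#'
#' @param predicted,observed numeric samples.
#' @param metric `"tv"`, `"kl"` or `"sinkhorn"`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param gene optional gene name carried into the result.
#' @param epsilon entropy regularization for the Sinkhorn metric.
#' @param tol,max_iter Sinkhorn solver controls.
#' @return List of class `permutation_test_result`: `gene`, `metric`,
#'   `observed` statistic, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(predicted, observed,
                             metric = c("tv", "kl", "sinkhorn"),
                             n_perm = 1000L, seed = 1L, gene = NA_character_,
                             epsilon = 1, tol = 1e-4, max_iter = 2000L) {
  metric <- match.arg(metric)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!length(predicted) || !length(observed)) stop("empty sample")
  stat <- switch(metric,
    tv = function(a, b) tv_distance(a, b),
    kl = function(a, b) kl_estimate(a, b),
    sinkhorn = function(a, b)
      suppressWarnings(sinkhorn_divergence(a, b, epsilon, tol, max_iter)))
  obs <- stat(predicted, observed)
  pool <- c(predicted, observed)
  n1 <- length(predicted)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n1)
    if (stat(pool[idx], pool[-idx]) >= obs) exceed <- exceed + 1L
  }
  structure(list(gene = gene, metric = metric, observed = obs,
                 p_value = (exceed + 1L) / (n_perm + 1L),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_test_result")
}

#' @exportS3Method base::print
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("permutation test (%s): observed %.4g, p = %.4g (%d permutations)\n",
              x$metric, x$observed, x$p_value, x$n_perm))
  invisible(x)
}

.silhouette_mean <- function(cl, X) {
  mean(cluster::silhouette(cl, stats::dist(X))[, "sil_width"])
}

#' Classify predicted states by reference-time subpopulations
#'
#' Fits k-means to the observed reference states (k chosen from
#' `k_candidates` by maximal mean silhouette score), then assigns each
#' predicted state the label of its nearest centroid (ties to the
#' lowest-index centroid). With the final snapshot as reference this labels
#' terminal fates; with the first snapshot, ancestral origins.
#'
#' @param reference_states cells-by-d latent matrix at the reference time.
#' @param predicted_states predicted latent states to label.
#' @param k_candidates candidate cluster counts (default 2:8), each below the
#'   number of reference points.
#' @param seed integer seed for k-means restarts.
#' @return List of class `subtrajectory_labels`: `labels` (integer per
#'   predicted state), `reference_labels`, `centers`, `k`,
#'   `silhouette` (mean width per candidate k), `scheme = "fate"`.
#' @export
classify_fates <- function(reference_states, predicted_states,
                           k_candidates = 2:8, seed = 1L) {
  X <- as.matrix(reference_states)
  k_candidates <- k_candidates[k_candidates >= 2L]
  if (max(k_candidates) >= nrow(X))
    stop("fewer reference points than the largest candidate k")
  set.seed(seed)
  fits <- lapply(k_candidates, function(k)
    stats::kmeans(X, centers = k, nstart = 10L, iter.max = 100L))
  sil <- vapply(seq_along(fits), function(i)
    .silhouette_mean(fits[[i]]$cluster, X), numeric(1))
  best <- which.max(sil)
  fit <- fits[[best]]
  P <- as.matrix(predicted_states)
  D <- cpp_sqdist(P, fit$centers)
  labels <- apply(D, 1L, which.min)  # which.min ties -> lowest index
  structure(list(labels = as.integer(labels),
                 reference_labels = fit$cluster, centers = fit$centers,
                 k = k_candidates[best],
                 silhouette = stats::setNames(sil, k_candidates),
                 scheme = "fate"),
            class = "subtrajectory_labels")
}

#' Stratify trajectories by phenotypic displacement
#'
#' Computes each cell's Euclidean displacement between its states at `t_pre`
#' and `t_post`, smooths the displacement histogram by a Gaussian KDE with
#' the Scott bandwidth \eqn{h = \hat\sigma n^{-1/5}}, finds local minima of
#' the density (peaks of the negated curve, with a prominence filter to
#' suppress numerical ripples), and uses the two smallest-x minima as cutoffs
#' into low/medium/high shift groups. With one minimum two groups are formed,
#' with none a single group (with a warning).
#'
#' @param trajectories a `trajectory_ensemble` from [integrate_trajectories()].
#' @param t_pre,t_post times on the trajectory grid, `t_pre < t_post`.
#' @param grid_n KDE evaluation grid size (default 512).
#' @param prominence minimum valley prominence as a fraction of the density
#'   maximum (default 1e-4).
#' @return List of class `displacement_stratification`: `displacement`
#'   per cell, `cutoffs`, integer `group` (1 = low), `summary` (mean, sd,
#'   IQR, CV, entropy in nats), and the KDE curve (`grid`, `density`).
#' @export
stratify_by_displacement <- function(trajectories, t_pre, t_post,
                                     grid_n = 512L, prominence = 1e-4) {
  if (t_pre >= t_post) stop("t_pre must be earlier than t_post")
  pre <- states_at(trajectories, t_pre)
  post <- states_at(trajectories, t_post)
  disp <- sqrt(rowSums((post - pre)^2))
  n <- length(disp)
  s <- stats::sd(disp)
  summary <- c(mean = mean(disp), sd = s, iqr = stats::IQR(disp),
               cv = if (is.finite(s) && mean(disp) > 0) s / mean(disp) else 0,
               entropy = NA_real_)
  if (!is.finite(s) || s == 0) {
    # degenerate: all displacements identical
    summary["entropy"] <- 0
    return(structure(list(displacement = disp, cutoffs = numeric(0),
                          group = rep(1L, n), summary = summary,
                          grid = NULL, density = NULL),
                     class = "displacement_stratification"))
  }
  h <- s * n^(-1 / 5)  # Scott bandwidth, 1-D Gaussian kernel
  grid <- seq(min(disp), max(disp), length.out = grid_n)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm((g - disp) / h)) / h, numeric(1))
  minima <- .local_minima(grid, dens, prominence * max(dens))
  cutoffs <- utils::head(sort(minima), 2L)
  if (length(cutoffs) == 0L)
    warning("no local minima in the displacement density; single group")
  group <- findInterval(disp, cutoffs) + 1L
  p <- graphics::hist(disp, breaks = grid, plot = FALSE)$counts
  p <- p / sum(p)
  summary["entropy"] <- -sum(p[p > 0] * log(p[p > 0]))
  structure(list(displacement = disp, cutoffs = cutoffs,
                 group = as.integer(group), summary = summary,
                 grid = grid, density = dens),
            class = "displacement_stratification")
}

# interior local minima of y(x) whose valley depth relative to the lower of
# the two flanking maxima exceeds `min_prom`
.local_minima <- function(x, y, min_prom) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) > 0) + 1L
  keep <- vapply(idx, function(i) {
    left_max <- max(y[1:i]); right_max <- max(y[i:n])
    min(left_max, right_max) - y[i] > min_prom
  }, logical(1))
  x[idx[keep]]
}

#' Normalized expression divergence between two trajectory groups
#'
#' For one gene: \eqn{\Delta G(t) = \bar g_1(t) - \bar g_2(t)} normalized by
#' \eqn{\max_t |\Delta G(t)|}, giving a profile in \eqn{[-1, 1]} (positive
#' where group 1 is higher). Genes whose |profile| crosses 0.5 are flagged as
#' substantially divergent, with the first crossing time reported; a drop
#' greater than 0.5 from an earlier profile value marks convergence.
#'
#' @param means1,means2 per-group mean expression over the common time grid.
#' @param times the time grid.
#' @return List: `profile`, `times`, `divergent` (logical), `t_divergence`
#'   (first |profile| >= 0.5 crossing, NA if none), `convergent`,
#'   `t_convergence`, `degenerate` (TRUE when the difference is identically
#'   zero and the profile is defined as 0).
#' @export
normalized_divergence <- function(means1, means2, times) {
  stopifnot(length(means1) == length(means2), length(means1) == length(times))
  dG <- means1 - means2
  m <- max(abs(dG))
  if (m == 0)
    return(list(profile = rep(0, length(dG)), times = times,
                divergent = FALSE, t_divergence = NA_real_,
                convergent = FALSE, t_convergence = NA_real_,
                degenerate = TRUE))
  prof <- dG / m
  cross <- which(abs(prof) >= 0.5)
  t_div <- if (length(cross)) {
    i <- cross[1L]
    if (i == 1L) times[1L] else {
      # linear interpolation to the 0.5 crossing between grid points
      a <- abs(prof[i - 1L]); b <- abs(prof[i])
      times[i - 1L] + (0.5 - a) / (b - a) * (times[i] - times[i - 1L])
    }
  } else NA_real_
  run_max <- cummax(abs(prof))
  drops <- which(run_max - abs(prof) > 0.5)
  t_conv <- if (length(drops)) times[drops[1L]] else NA_real_
  list(profile = prof, times = times,
       divergent = length(cross) > 0L, t_divergence = t_div,
       convergent = length(drops) > 0L, t_convergence = t_conv,
       degenerate = FALSE)
}

#' Differential expression between two cell groups
#'
#' Per gene: `log2((mean_a + c) / (mean_b + c))` with pseudocount `c`, a
#' Welch two-sample t-test p-value, and Benjamini-Hochberg FDR. A gene with
#' zero variance in both groups gets p = 1 by convention.
#'
#' @param group_a,group_b cells-by-genes matrices (>= 2 cells each) over the
#'   same genes.
#' @param pseudocount stabilizer for the fold change on (log-)normalized data.
#' @return data.frame with columns `gene`, `log2fc`, `p`, `fdr`, `n_a`, `n_b`.
#' @export
deg_analysis <- function(group_a, group_b, pseudocount = 1e-9) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (nrow(A) < 2L || nrow(B) < 2L) stop("both groups need at least 2 cells")
  if (ncol(A) != ncol(B)) stop("gene sets differ between groups")
  genes <- colnames(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(A)))
  res <- vapply(seq_len(ncol(A)), function(j) {
    a <- A[, j]; b <- B[, j]
    lfc <- log2((mean(a) + pseudocount) / (mean(b) + pseudocount))
    p <- if (stats::var(a) == 0 && stats::var(b) == 0) 1
         else stats::t.test(a, b)$p.value
    c(lfc, p)
  }, numeric(2))
  data.frame(gene = genes, log2fc = res[1L, ], p = res[2L, ],
             fdr = stats::p.adjust(res[2L, ], method = "BH"),
             n_a = nrow(A), n_b = nrow(B), row.names = NULL)
}
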