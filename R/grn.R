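## Stochastic gene-regulatory-network simulator: shifted Hill regulation,
## first-order production/degradation kinetics and multiplicative noise,
## integrated by Euler-Maruyama. Used to generate synthetic
## epithelial-mesenchymal transition (EMT) time courses that emulate sparse
## time-stamped scRNA-seq sampling.

#' Shifted Hill regulation function
#'
#' Saturating regulation factor \eqn{HS(x) = \lambda + (1-\lambda)\,/\,(1 +
#' (x/\Theta)^n)} interpolating between 1 (no regulator, \eqn{x = 0}) and the
#' fold change \eqn{\lambda} (saturating regulator). \eqn{\lambda > 1} encodes
#' activation, \eqn{0 < \lambda < 1} inhibition.
#'
#' @param x regulator expression level(s), non-negative.
#' @param lam fold-change parameter \eqn{\lambda}.
#' @param theta threshold \eqn{\Theta > 0} at which regulation is half-maximal.
#' @param n Hill coefficient, a positive integer; larger values give steeper
#'   switching around \eqn{\Theta}.
#' @return Dimensionless factor between `min(1, lam)` and `max(1, lam)`.
#' @export
#' @examples
#' shifted_hill(0, lam = 5, theta = 10, n = 2)   # 1: no regulator
#' shifted_hill(10, lam = 5, theta = 10, n = 2)  # (1 + 5) / 2: half occupancy
shifted_hill <- function(x, lam, theta, n) {
  if (any(theta <= 0)) stop("theta must be positive")
  if (any(n < 1)) stop("Hill coefficient n must be >= 1")
  lam + (1 - lam) / (1 + (x / theta)^n)
}

#' Construct a gene-regulatory-network model
#'
#' Bundles the connection matrix \eqn{J} (entries +1 activation, -1
#' inhibition, 0 none; `J[i, j]` is the action of gene `j` on gene `i`) with
#' per-gene production rates `g`, degradation rates `k`, per-edge shifted-Hill
#' parameters (`lam`, `theta`, `n`) and the multiplicative-noise magnitude
#' `D`.
#'
#' @param J square integer matrix in \{-1, 0, +1\}; rows are targets, columns
#'   regulators. Row/column names, if present, are taken as gene names.
#' @param g,k per-gene production and degradation rates, strictly positive.
#' @param lam,theta,n matrices of edge parameters, used only where `J != 0`.
#'   `lam` must exceed 1 on activating edges and lie in (0, 1) on inhibiting
#'   edges; `theta` must be positive and `n` a positive integer.
#' @param D noise magnitude (default 1); the noise term is `D * x_i * eta_i`
#'   with unit-variance white noise `eta_i`.
#' @return An object of class `grn_model`.
#' @export
grn_model <- function(J, g, k, lam, theta, n, D = 1) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("J must be square")
  if (!all(J %in% c(-1, 0, 1))) stop("J entries must be in {-1, 0, +1}")
  G <- nrow(J)
  if (length(g) != G || length(k) != G) stop("g and k must have one entry per gene")
  if (any(g <= 0) || any(k <= 0)) stop("production and degradation rates must be strictly positive")
  if (D < 0) stop("noise magnitude D must be >= 0")
  lam <- as.matrix(lam); theta <- as.matrix(theta); n <- as.matrix(n)
  for (M in list(lam, theta, n))
    if (!all(dim(M) == dim(J))) stop("edge parameter matrices must match dim(J)")
  edge <- J != 0
  if (any(edge)) {
    if (any(theta[edge] <= 0)) stop("theta must be positive on every edge")
    if (any(n[edge] < 1) || any(n[edge] != round(n[edge])))
      stop("Hill coefficients must be positive integers")
    act <- J == 1; inh <- J == -1
    if (any(lam[act] <= 1)) stop("lam must be > 1 on activating edges")
    if (any(lam[inh] <= 0) || any(lam[inh] >= 1)) stop("lam must lie in (0, 1) on inhibiting edges")
  }
  genes <- rownames(J)
  if (is.null(genes)) genes <- paste0("g", seq_len(G))
  structure(list(J = J, g = as.numeric(g), k = as.numeric(k), lam = lam,
                 theta = theta, n = n, D = D, genes = genes),
            class = "grn_model")
}

#' @exportS3Method base::print
print.grn_model <- function(x, ...) {
  cat(sprintf("grn_model: %d genes, %d activating / %d inhibiting edges, D = %g\n",
              length(x$genes), sum(x$J == 1), sum(x$J == -1), x$D))
  invisible(x)
}

#' Deterministic drift of the GRN dynamics
#'
#' Component \eqn{i} is \eqn{g_i \prod_{j: J_{ij} \ne 0} HS(x_j) - k_i x_i};
#' the product over an empty regulator set is 1.
#'
#' @param x state vector (one entry per gene) or a cells-by-genes matrix of
#'   states evaluated row-wise.
#' @param model a [grn_model()].
#' @return Drift with the same shape as `x` (rate units).
#' @export
grn_drift <- function(x, model) {
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, nrow = 1L) else as.matrix(x)
  G <- length(model$genes)
  if (ncol(X) != G) stop("state dimension does not match the model's gene count")
  prodHS <- matrix(1, nrow(X), G)
  idx <- which(model$J != 0, arr.ind = TRUE)
  for (e in seq_len(nrow(idx))) {
    i <- idx[e, 1L]; j <- idx[e, 2L]
    prodHS[, i] <- prodHS[, i] *
      shifted_hill(X[, j], model$lam[i, j], model$theta[i, j], model$n[i, j])
  }
  out <- sweep(prodHS, 2L, model$g, "*") - sweep(X, 2L, model$k, "*")
  if (vec_in) drop(out) else out
}

#' Simulate the GRN stochastic differential equations
#'
#' Euler-Maruyama integration of \eqn{dx_i = \mathrm{drift}_i\,dt + D x_i
#' \sqrt{dt}\,\xi}, \eqn{\xi \sim N(0,1)} i.i.d. per gene, replicate and step.
#' Because the noise is proportional to \eqn{x_i}, the state \eqn{x = 0} is
#' absorbing in the exact dynamics; states are clipped at 0 after each step to
#' preserve that property under discretization.
#'
#' @param model a [grn_model()].
#' @param x0 initial state: a vector (shared by all replicates) or a
#'   replicates-by-genes matrix.
#' @param dt time step, > 0.
#' @param t_end duration, >= 0.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @param n_rep number of replicates when `x0` is a vector.
#' @return An object of class `grn_trajectories`: list with `times` (the
#'   simulation grid) and `values`, a replicate x time x gene array.
#' @export
simulate_grn <- function(model, x0, dt, t_end, seed = 1L, n_rep = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (t_end < 0) stop("t_end must be non-negative")
  G <- length(model$genes)
  X <- if (is.null(dim(x0))) {
    if (length(x0) != G) stop("x0 length does not match gene count")
    matrix(rep(as.numeric(x0), each = if (is.null(n_rep)) 1L else n_rep),
           nrow = if (is.null(n_rep)) 1L else n_rep, ncol = G)
  } else as.matrix(x0)
  if (any(X < 0)) stop("initial states must be non-negative")
  R <- nrow(X)
  n_steps <- round(t_end / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  values <- array(NA_real_, dim = c(R, n_steps + 1L, G),
                  dimnames = list(NULL, NULL, model$genes))
  set.seed(seed)
  values[, 1L, ] <- X
  sq <- sqrt(dt)
  for (m in seq_len(n_steps)) {
    Xprev <- X
    X <- X + dt * grn_drift(X, model)
    if (model$D > 0)
      X <- X + model$D * Xprev * sq * matrix(stats::rnorm(R * G), R, G)
    X[X < 0] <- 0
    values[, m + 1L, ] <- X
  }
  structure(list(times = times, values = values, seed = seed, genes = model$genes),
            class = "grn_trajectories")
}

#' Sample an ensemble of GRN parameter sets
#'
#' Draws `n_sets` kinetic parameterizations of a fixed topology from
#' independent uniform ranges, mirroring ensemble-based GRN modelling:
#' production and degradation rates per gene, a fold change per edge (from the
#' activation range on activating edges and the inhibition range on inhibiting
#' ones), a threshold per edge expressed as a multiple of the regulator's
#' unregulated scale \eqn{g_j / k_j}, and an integer Hill coefficient.
#'
#' @param J connection matrix (see [grn_model()]).
#' @param n_sets number of parameter sets, >= 1.
#' @param ranges named list of `c(low, high)` bounds with elements `g`, `k`,
#'   `lam_act`, `lam_inh`, `theta_frac` (threshold as a fraction of the
#'   regulator's \eqn{g/k} scale) and `n` (integer bounds). See
#'   [default_grn_ranges()].
#' @param seed integer seed.
#' @param D noise magnitude passed to each model.
#' @return List of [grn_model()] objects.
#' @export
sample_grn_ensemble <- function(J, n_sets, ranges = default_grn_ranges(),
                                seed = 1L, D = 1) {
  stopifnot(n_sets >= 1)
  for (nm in c("g", "k", "lam_act", "lam_inh", "theta_frac", "n")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2L) stop("ranges$", nm, " must be c(low, high)")
    if (r[1L] > r[2L]) stop("inverted bounds in ranges$", nm)
  }
  J <- as.matrix(J)
  G <- nrow(J)
  set.seed(seed)
  lapply(seq_len(n_sets), function(s) {
    g <- stats::runif(G, ranges$g[1L], ranges$g[2L])
    k <- stats::runif(G, ranges$k[1L], ranges$k[2L])
    lam <- matrix(1, G, G); theta <- matrix(1, G, G); n <- matrix(1, G, G)
    idx <- which(J != 0, arr.ind = TRUE)
    for (e in seq_len(nrow(idx))) {
      i <- idx[e, 1L]; j <- idx[e, 2L]
      lam[i, j] <- if (J[i, j] == 1)
        stats::runif(1, ranges$lam_act[1L], ranges$lam_act[2L])
      else stats::runif(1, ranges$lam_inh[1L], ranges$lam_inh[2L])
      theta[i, j] <- (g[j] / k[j]) *
        stats::runif(1, ranges$theta_frac[1L], ranges$theta_frac[2L])
      n[i, j] <- sample(seq(ranges$n[1L], ranges$n[2L]), 1L)
    }
    grn_model(J, g, k, lam, theta, n, D = D)
  })
}

#' Default parameter-sampling ranges for GRN ensembles
#'
#' Biologically plausible defaults: production rates 1-100 expression/time,
#' degradation rates 0.1-1 per time (lifetimes 1-10 time units), activating
#' fold changes 1-10, inhibiting fold changes 0.1-1, thresholds 2%-198% of
#' the regulator's unregulated steady state, Hill coefficients 1-6.
#'
#' @return Named list of `c(low, high)` bounds.
#' @export
default_grn_ranges <- function() {
  list(g = c(1, 100), k = c(0.1, 1), lam_act = c(1, 10), lam_inh = c(0.1, 1),
       theta_frac = c(0.02, 1.98), n = c(1, 6))
}

#' Extract time-stamped snapshots from simulated trajectories
#'
#' Emulates temporally sparse scRNA-seq sampling: each requested time yields a
#' cells-by-genes matrix whose rows are the replicates at the nearest grid
#' point (ties broken toward the earlier index).
#'
#' @param trajectories a `grn_trajectories` object from [simulate_grn()].
#' @param sample_times times to sample, each within the simulated range.
#' @return A [snapshot_series()].
#' @export
subsample_snapshots <- function(trajectories, sample_times) {
  tg <- trajectories$times
  if (any(sample_times < min(tg)) || any(sample_times > max(tg)))
    stop("requested sample time outside the simulated range")
  mats <- lapply(sample_times, function(ts) {
    d <- abs(tg - ts)
    idx <- which(d == min(d))[1L]  # ties -> earlier grid point
    m <- trajectories$values[, idx, , drop = FALSE]
    dim(m) <- dim(trajectories$values)[c(1L, 3L)]
    colnames(m) <- trajectories$genes
    m
  })
  snapshot_series(mats, times = sample_times, gene_names = trajectories$genes)
}

#' Read a GRN topology from a delimited text file
#'
#' Expects a whitespace-delimited square integer matrix with a header row of
#' gene names (rows are target genes in the same order as the columns).
#'
#' @param path file path. The package ships a constructed 26-gene EMT-like
#'   topology (core microRNA-200/ZEB and SNAIL/miR-34 double-negative feedback
#'   loops with epithelial and mesenchymal marker genes) at
#'   `system.file("extdata", "emt_grn_26_synthetic.txt", package = "profet")`;
#'   this network is synthetic and editable, not a published reconstruction.
#' @return Integer matrix with gene dimnames, usable as `J` in [grn_model()].
#' @export
read_grn_topology <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  J <- as.matrix(tab)
  if (nrow(J) != ncol(J)) stop("topology matrix must be square")
  rownames(J) <- colnames(J)
  storage.mode(J) <- "integer"
  if (!all(J %in% c(-1L, 0L, 1L))) stop("topology entries must be in {-1, 0, +1}")
  J
}
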