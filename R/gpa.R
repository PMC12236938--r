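## Generative particle algorithm: variational estimation of the
## Lipschitz-regularized KL divergence via a spectrally normalized neural
## dual potential, and forward-Euler transport of source particles down the
## potential's gradient, recording time-labelled velocities for
## force-matching.

#' Convex conjugate of x log x
#'
#' The Legendre transform of \eqn{f(x) = x \log x} is \eqn{f^*(y) =
#' e^{y - 1}}; it appears in the variational (dual) representation of the KL
#' divergence. The exponent is clamped at 30 to guard against overflow while
#' the potential is far from optimal.
#'
#' @param y numeric.
#' @return `exp(pmin(y - 1, 30))`.
#' @export
fstar <- function(y) exp(pmin(y - 1, 30))

#' GPA configuration
#'
#' @param L global Lipschitz bound on the dual potential (default 1; bounds
#'   the transport speed).
#' @param dt forward-Euler step size for the particle update.
#' @param max_iters maximum number of outer transport iterations.
#' @param stop_threshold stop once the fitted divergence estimate falls below
#'   this value (default 0.05).
#' @param inner_iters gradient-ascent steps per potential fit.
#' @param inner_iters_init gradient-ascent steps for the very first fit
#'   (warm-up); subsequent fits warm-start from the previous potential and
#'   need fewer steps.
#' @param inner_lr Adam learning rate for the inner maximization.
#' @param hidden hidden-layer widths of the potential network.
#' @param power_iters power-iteration steps per spectral-norm update.
#' @param warm_start reuse the previous iteration's potential weights as the
#'   starting point of the next fit.
#' @param seed integer seed.
#' @return List of class `gpa_config`.
#' @export
gpa_config <- function(L = 1, dt = 0.1, max_iters = 150L, stop_threshold = 0.05,
                       inner_iters = 50L, inner_iters_init = 500L,
                       inner_lr = 1e-3,
                       hidden = c(128L, 128L, 128L), power_iters = 5L,
                       warm_start = TRUE, seed = 1L) {
  structure(list(L = L, dt = dt, max_iters = as.integer(max_iters),
                 stop_threshold = stop_threshold,
                 inner_iters = as.integer(inner_iters),
                 inner_iters_init = as.integer(inner_iters_init),
                 inner_lr = inner_lr,
                 hidden = as.integer(hidden), power_iters = as.integer(power_iters),
                 warm_start = warm_start, seed = as.integer(seed)),
            class = "gpa_config")
}

#' Variational divergence objective
#'
#' The inner objective of the regularized KL estimate:
#' \eqn{\frac1N \sum_i \phi(Y_i) - \frac1M \sum_j f^*(\phi(X_j))}, where `Y`
#' are the current particles and `X` the target sample. Maximized over
#' L-Lipschitz potentials it estimates the Lipschitz-regularized KL
#' divergence from the particle distribution to the target.
#'
#' @param phi a potential network (`profet_mlp`, scalar output).
#' @param source N-by-d matrix of current particle positions.
#' @param target M-by-d matrix of target positions.
#' @return Scalar divergence estimate.
#' @export
variational_objective <- function(phi, source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 1L || nrow(target) < 1L) stop("empty particle set")
  mean(mlp_predict(phi, source)) - mean(fstar(mlp_predict(phi, target)))
}

# One fused forward/backward pass of the objective over both clouds;
# returns the objective value and parameter gradients (for ascent).
.objective_grads <- function(phi, source, target) {
  N <- nrow(source); M <- nrow(target)
  Z <- rbind(source, target)
  fwd <- mlp_forward(phi, Z)
  out <- fwd$out
  phiY <- out[seq_len(N), 1L]
  phiX <- out[N + seq_len(M), 1L]
  fsX <- fstar(phiX)
  dout <- matrix(c(rep(1 / N, N), -fsX / M), ncol = 1L)
  bp <- mlp_backprop(phi, fwd, dout)
  list(value = mean(phiY) - mean(fsX), gW = bp$gW, gb = bp$gb)
}

#' Fit the Lipschitz-constrained dual potential
#'
#' Gradient-ascent (Adam) on [variational_objective()] with a hard
#' spectral-norm projection after every update so the network stays
#' L-Lipschitz; the final projection uses exact spectral norms, making the
#' gradient-norm bound \eqn{\|\nabla\phi\| \le L} hold to machine precision.
#'
#' @param source,target particle position matrices.
#' @param config a [gpa_config()].
#' @param phi optional potential to warm-start from.
#' @return List with the fitted `phi`, the Adam `state`, the final `objective`
#'   and the inner objective `trace`.
#' @export
fit_potential <- function(source, target, config = gpa_config(), phi = NULL,
                          state = NULL) {
  d <- ncol(as.matrix(source))
  cap <- config$L^(1 / (length(config$hidden) + 1L))
  n_inner <- config$inner_iters
  if (is.null(phi)) {
    phi <- mlp_new(d, config$hidden, 1L, activation = "relu", seed = config$seed)
    phi <- mlp_spectral_project(phi, cap, exact = TRUE)
    if (!is.null(config$inner_iters_init)) n_inner <- config$inner_iters_init
  }
  if (is.null(state)) state <- adam_init(phi)
  trace <- numeric(n_inner)
  for (i in seq_len(n_inner)) {
    gr <- .objective_grads(phi, source, target)
    if (!is.finite(gr$value))
      stop("variational objective diverged (NaN); lower gpa inner_lr")
    trace[i] <- gr$value
    st <- adam_step(phi, state, gr, lr = config$inner_lr, maximize = TRUE)
    phi <- st$net; state <- st$state
    phi <- mlp_spectral_project(phi, cap, power_iters = config$power_iters)
  }
  phi <- mlp_spectral_project(phi, cap, exact = TRUE)
  obj <- variational_objective(phi, source, target)
  tail10 <- trace[seq(max(1L, floor(0.9 * length(trace))), length(trace))]
  drop10 <- max(tail10) - tail10[length(tail10)]
  if (length(tail10) > 2L && stats::cor(seq_along(tail10), tail10) < -0.5 &&
      drop10 > 0.1 * max(abs(tail10)))
    warning("inner objective decreasing over the last 10% of iterations")
  list(phi = phi, state = state, objective = obj, trace = trace)
}

#' Move particles one forward-Euler step down the potential gradient
#'
#' @param particles N-by-d position matrix.
#' @param phi fitted potential.
#' @param dt step size, > 0.
#' @return Updated positions `particles - dt * grad(phi)`.
#' @export
euler_step <- function(particles, phi, dt) {
  if (dt <= 0) stop("dt must be positive")
  gr <- mlp_input_grad(phi, particles)
  if (!all(is.finite(gr))) stop("non-finite potential gradient")
  particles - dt * gr
}

#' Expected kinetic energy of the particle ensemble
#'
#' Mean over particles of \eqn{\|\nabla\phi(Y_i)\|^2}; its decay quantifies
#' the slowing of the flow as particles approach the target.
#'
#' @param particles N-by-d position matrix.
#' @param phi fitted potential.
#' @return Non-negative scalar.
#' @export
kinetic_energy <- function(particles, phi) {
  mean(rowSums(mlp_input_grad(phi, particles)^2))
}

#' Run the generative particle algorithm between two snapshots
#'
#' Alternates potential fitting and forward-Euler particle updates, recording
#' the time-labelled velocity `(x, n * dt, -grad(phi_n)(x))` of every particle
#' at every iteration. Stops as soon as the fitted divergence estimate drops
#' below `config$stop_threshold`, or after `config$max_iters` iterations.
#'
#' @param source_snapshot N-by-d matrix of source positions (latent space).
#' @param target_snapshot M-by-d matrix of target positions.
#' @param config a [gpa_config()].
#' @param subinterval_id integer tag carried into the velocity records.
#' @return Object of class `gpa_result`: `particles` (final positions),
#'   `velocities` (data.frame with columns `x1..xd`, `t_local`, `v1..vd`,
#'   `iter`, `subinterval`), `horizon` (= iterations run * dt), `objective`
#'   trace across outer iterations, `kinetic` energy trace, `stopped_early`.
#' @export
run_gpa <- function(source_snapshot, target_snapshot, config = gpa_config(),
                    subinterval_id = 1L) {
  Y <- as.matrix(source_snapshot)
  X <- as.matrix(target_snapshot)
  if (ncol(Y) != ncol(X)) stop("source and target dimension mismatch")
  d <- ncol(Y); N <- nrow(Y)
  diam <- sqrt(max(rowSums(sweep(rbind(Y, X), 2L, colMeans(rbind(Y, X)))^2))) * 2
  if (diam > 0 && config$dt * config$L > 0.5 * diam)
    warning("dt * L exceeds half the data diameter; consider a smaller dt")
  set.seed(config$seed)
  phi <- NULL; state <- NULL
  obj_trace <- numeric(0)
  kin_trace <- numeric(0)
  recs <- vector("list", config$max_iters)
  n_run <- 0L
  stopped <- FALSE
  for (n in seq_len(config$max_iters) - 1L) {
    fit <- fit_potential(Y, X, config, phi = phi, state = state)
    if (config$warm_start) { phi <- fit$phi; state <- fit$state }
    obj_trace <- c(obj_trace, fit$objective)
    if (fit$objective < config$stop_threshold) { stopped <- TRUE; break }
    g <- mlp_input_grad(fit$phi, Y)
    if (!all(is.finite(g))) stop("non-finite potential gradient at iteration ", n)
    kin_trace <- c(kin_trace, mean(rowSums(g^2)))
    recs[[n + 1L]] <- cbind(Y, n * config$dt, -g)
    Y <- Y - config$dt * g
    n_run <- n_run + 1L
  }
  if (!stopped && length(obj_trace) >= 4L) {
    q <- max(2L, floor(0.25 * length(obj_trace)))
    last <- obj_trace[seq(length(obj_trace) - q + 1L, length(obj_trace))]
    if (all(diff(last) >= 0))
      warning(sprintf("no progress: objective non-decreasing over final %d iterations (last = %.4f)",
                      q, obj_trace[length(obj_trace)]))
  }
  vel <- do.call(rbind, recs[seq_len(n_run)])
  if (is.null(vel)) vel <- matrix(numeric(0), ncol = 2L * d + 1L)
  vel <- as.data.frame(vel)
  names(vel) <- c(paste0("x", seq_len(d)), "t_local", paste0("v", seq_len(d)))
  vel$iter <- if (nrow(vel)) rep(seq_len(n_run) - 1L, each = N) else integer(0)
  vel$subinterval <- if (nrow(vel)) subinterval_id else integer(0)
  structure(list(particles = Y, velocities = vel,
                 horizon = n_run * config$dt, dt = config$dt, d = d,
                 iterations = n_run, objective = obj_trace,
                 kinetic = kin_trace, stopped_early = stopped,
                 L = config$L),
            class = "gpa_result")
}

#' @exportS3Method base::print
print.gpa_result <- function(x, ...) {
  cat(sprintf("gpa_result: %d iterations (%s), final divergence estimate %.4f, %d velocity records\n",
              x$iterations, if (x$stopped_early) "stopped early" else "budget reached",
              x$objective[length(x$objective)], nrow(x$velocities)))
  invisible(x)
}
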