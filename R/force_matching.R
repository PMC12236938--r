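## Force-matching: align per-subinterval GPA velocity samples onto the
## physical time axis, train a global time-dependent neural velocity field on
## them by least squares, and integrate continuous trajectories.

#' Align local GPA simulation times to the physical time axis
#'
#' Each subinterval `i` of the snapshot series was transported by GPA on its
#' own local clock `t in [0, H_i]` (`H_i` = iterations * dt). The default
#' mode maps each local clock affinely onto its own observation interval
#' `[t_i, t_{i+1}]`, anchoring trajectories to the experimental stamps. The
#' alternative `"longest-horizon"` mode dilates all local clocks by the single
#' factor `(t_{i+1} - t_i) / max_i H_i`, so subintervals whose transport
#' finished early cover only part of their observation window.
#'
#' @param records velocity data.frame(s) from [run_gpa()] (or a list of
#'   `gpa_result` objects), carrying `t_local` and `subinterval` columns.
#' @param observation_times ordered snapshot stamps `t_0 < ... < t_K`.
#' @param horizons named or ordered numeric vector of local horizons `H_i`,
#'   one per subinterval; taken from the `gpa_result`s when those are given.
#' @param mode `"per-interval"` (default) or `"longest-horizon"`.
#' @return Single data.frame of velocity samples with a global time column
#'   `s`, strictly increasing in local time within each subinterval. The
#'   velocity columns are rescaled by the chain rule (`v * dt_local/ds`) so
#'   they are derivatives with respect to physical time; integrating the
#'   matched field in `s` then reproduces the transport on the experimental
#'   clock.
#' @export
align_times <- function(records, observation_times,
                        horizons = NULL, mode = c("per-interval", "longest-horizon")) {
  mode <- match.arg(mode)
  if (is.list(records) && !is.data.frame(records) &&
      all(vapply(records, inherits, TRUE, "gpa_result"))) {
    horizons <- vapply(records, function(r) r$horizon, numeric(1))
    records <- do.call(rbind, lapply(records, function(r) r$velocities))
  }
  if (is.unsorted(observation_times, strictly = TRUE))
    stop("observation_times must be strictly increasing")
  K <- length(observation_times) - 1L
  ids <- sort(unique(records$subinterval))
  if (length(ids) && (min(ids) < 1L || max(ids) > K))
    stop("record with unknown subinterval id")
  if (is.null(horizons)) stop("horizons required when records is a data.frame")
  if (length(horizons) < max(ids)) stop("one horizon per subinterval required")
  Hmax <- max(horizons)
  vcols <- grep("^v[0-9]+$", names(records), value = TRUE)
  s <- numeric(nrow(records))
  for (i in ids) {
    sel <- records$subinterval == i
    t0 <- observation_times[i]; t1 <- observation_times[i + 1L]
    # ds/dt_local: the dilation of the local clock onto the physical axis
    dil <- if (mode == "per-interval") (t1 - t0) / horizons[i]
           else (t1 - t0) / Hmax
    s[sel] <- t0 + records$t_local[sel] * dil
    records[sel, vcols] <- records[sel, vcols] / dil
  }
  records$s <- s
  attr(records, "observation_range") <- range(observation_times)
  records
}

#' Force-matching configuration
#'
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param epochs number of gradient updates (one sampled minibatch each).
#' @param hidden hidden-layer widths of the velocity network.
#' @param sn_cap per-layer spectral-norm cap (default 4); keeps the field
#'   Lipschitz in `(x, s)` by construction -- the global Lipschitz constant is
#'   bounded by `sn_cap^n_layers` on the standardized coordinates -- while
#'   leaving enough expressivity for steep transitions between subintervals
#'   (tight caps make the constrained fit unstable).
#' @param holdout fraction of samples held out to monitor overfitting.
#' @param seed integer seed.
#' @return List of class `fm_config`.
#' @export
fm_config <- function(batch = 256L, lr = 1e-3, epochs = 3000L,
                      hidden = c(64L, 64L, 64L, 64L), sn_cap = 4,
                      holdout = 0.1, seed = 1L) {
  structure(list(batch = as.integer(batch), lr = lr, epochs = as.integer(epochs),
                 hidden = as.integer(hidden), sn_cap = sn_cap,
                 holdout = holdout, seed = as.integer(seed)),
            class = "fm_config")
}

.vel_cols <- function(samples) {
  d <- sum(grepl("^x[0-9]+$", names(samples)))
  list(x = paste0("x", seq_len(d)), v = paste0("v", seq_len(d)), d = d)
}

#' Mean squared force-matching loss
#'
#' Mean over samples of \eqn{\|v_\theta(x, s) - v\|^2}: zero iff the field
#' reproduces every recorded velocity.
#'
#' @param field a `velocity_field` (or any function `f(X, s)` returning
#'   velocities row-wise).
#' @param samples aligned velocity samples from [align_times()].
#' @return Non-negative scalar.
#' @export
force_matching_loss <- function(field, samples) {
  if (nrow(samples) == 0L) stop("empty velocity sample set")
  cols <- .vel_cols(samples)
  pred <- predict_velocity(field, as.matrix(samples[cols$x]), samples$s)
  mean(rowSums((pred - as.matrix(samples[cols$v]))^2))
}

#' Train the global time-dependent velocity field
#'
#' Minibatch Adam on the force-matching loss over all aligned velocity
#' samples. Layers are spectrally capped after every update. A held-out split
#' guards against overfitting (warning if held-out loss exceeds twice the
#' training loss).
#'
#' @param samples aligned velocity samples with columns `x1..xd`, `s`,
#'   `v1..vd`.
#' @param config an [fm_config()].
#' @return Object of class `velocity_field` with the trained network, the
#'   unified `time_domain` and the final training/validation losses.
#' @export
train_velocity_field <- function(samples, config = fm_config()) {
  if (nrow(samples) == 0L) stop("empty velocity sample set")
  cols <- .vel_cols(samples)
  d <- cols$d
  X <- cbind(as.matrix(samples[cols$x]), samples$s)
  V <- as.matrix(samples[cols$v])
  # standardize inputs and velocity targets; the network is fit on z-scored
  # coordinates and the scales are folded back in at prediction time
  x_center <- colMeans(X)
  x_scale <- pmax(apply(X, 2L, stats::sd), 1e-12)
  v_center <- colMeans(V)
  v_scale <- pmax(apply(V, 2L, stats::sd), 1e-12)
  X <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  V <- sweep(sweep(V, 2L, v_center), 2L, v_scale, "/")
  set.seed(config$seed)
  n <- nrow(X)
  n_val <- floor(config$holdout * n)
  val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  net <- mlp_new(d + 1L, config$hidden, d, activation = "tanh",
                 seed = config$seed)
  net <- mlp_spectral_project(net, config$sn_cap, exact = TRUE)
  state <- adam_init(net)
  loss <- NA_real_
  for (e in seq_len(config$epochs)) {
    idx <- if (length(tr_idx) > config$batch)
      sample(tr_idx, config$batch) else tr_idx
    fwd <- mlp_forward(net, X[idx, , drop = FALSE])
    resid <- fwd$out - V[idx, , drop = FALSE]
    loss <- mean(rowSums(resid^2))
    if (!is.finite(loss)) stop("force-matching loss became NaN; lower fm lr")
    gr <- mlp_backprop(net, fwd, 2 * resid / length(idx))
    # step decay: 1/3 of the base rate for the middle third of training and
    # 1/10 for the final third, settling the minibatch noise
    lr_e <- config$lr * c(1, 1/3, 0.1)[1L + (3L * (e - 1L)) %/% config$epochs]
    st <- adam_step(net, state, gr, lr = lr_e)
    net <- st$net; state <- st$state
    net <- mlp_spectral_project(net, config$sn_cap)
  }
  net <- mlp_spectral_project(net, config$sn_cap, exact = TRUE)
  # the unified domain is the full observation window when known (alignment
  # maps each local horizon onto it); otherwise the sampled time range
  td <- attr(samples, "observation_range")
  if (is.null(td)) td <- range(samples$s)
  field <- structure(list(network = net, d = d,
                          x_center = x_center, x_scale = x_scale,
                          v_center = v_center, v_scale = v_scale,
                          time_domain = td,
                          train_loss = NA_real_, val_loss = NA_real_),
                     class = "velocity_field")
  tr_loss <- .field_mse(field, X[tr_idx, , drop = FALSE], V[tr_idx, , drop = FALSE])
  field$train_loss <- tr_loss
  if (length(val_idx)) {
    field$val_loss <- .field_mse(field, X[val_idx, , drop = FALSE],
                                 V[val_idx, , drop = FALSE])
    if (is.finite(field$val_loss) && field$val_loss > 2 * tr_loss)
      warning("held-out force-matching loss exceeds twice the training loss")
  }
  field
}

# mean squared error on standardized arrays, reported on the original
# velocity scale
.field_mse <- function(field, Xs, V) {
  if (nrow(Xs) == 0L) return(NA_real_)
  resid <- mlp_predict(field$network, Xs) - V
  mean(rowSums(sweep(resid, 2L, field$v_scale, "*")^2))
}

#' Evaluate a velocity field
#'
#' @param field a `velocity_field` or plain function `f(X, s)`.
#' @param X positions, N-by-d matrix.
#' @param s time(s): scalar or length-N vector.
#' @return N-by-d matrix of velocities.
#' @export
predict_velocity <- function(field, X, s) UseMethod("predict_velocity")

#' @export
predict_velocity.velocity_field <- function(field, X, s) {
  X <- as.matrix(X)
  if (length(s) == 1L) s <- rep(s, nrow(X))
  Z <- cbind(X, s)
  Z <- sweep(sweep(Z, 2L, field$x_center), 2L, field$x_scale, "/")
  sweep(sweep(mlp_predict(field$network, Z), 2L, field$v_scale, "*"),
        2L, field$v_center, "+")
}

#' @export
predict_velocity.function <- function(field, X, s) {
  X <- as.matrix(X)
  out <- field(X, s)
  matrix(out, nrow = nrow(X))
}

#' @exportS3Method base::print
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: d = %d, time domain [%g, %g], train loss %.4g\n",
              x$d, x$time_domain[1L], x$time_domain[2L], x$train_loss))
  invisible(x)
}

#' Integrate trajectories through a velocity field
#'
#' Forward Euler: \eqn{x_{m+1} = x_m + h\,v_\theta(x_m, s_m)} with
#' `h = (s_end - s_start) / n_steps`.
#'
#' @param field a `velocity_field` (or plain function `f(X, s)`).
#' @param starts N-by-d matrix of start states.
#' @param s_start,s_end integration limits; extrapolating beyond the field's
#'   training time domain triggers a warning.
#' @param n_steps number of Euler steps, >= 1.
#' @return Object of class `trajectory_ensemble`: `times` (grid of length
#'   `n_steps + 1`) and `states`, a cell x time x d array.
#' @export
integrate_trajectories <- function(field, starts, s_start, s_end, n_steps) {
  if (n_steps < 1L) stop("n_steps must be >= 1")
  starts <- as.matrix(starts)
  if (inherits(field, "velocity_field")) {
    td <- field$time_domain
    if (s_start < td[1L] - 1e-9 || s_end > td[2L] + 1e-9)
      warning("integration range extends beyond the field's training time domain (extrapolating)")
  }
  h <- (s_end - s_start) / n_steps
  grid <- seq(s_start, s_end, length.out = n_steps + 1L)
  N <- nrow(starts); d <- ncol(starts)
  states <- array(NA_real_, dim = c(N, n_steps + 1L, d))
  X <- starts
  states[, 1L, ] <- X
  for (m in seq_len(n_steps)) {
    X <- X + h * predict_velocity(field, X, grid[m])
    if (!all(is.finite(X))) {
      bad <- which(!is.finite(rowSums(X)))[1L]
      stop(sprintf("non-finite state at step %d (trajectory %d)", m, bad))
    }
    states[, m + 1L, ] <- X
  }
  structure(list(times = grid, states = states),
            class = "trajectory_ensemble")
}

#' Extract trajectory states at a given time
#'
#' @param trajectories a `trajectory_ensemble`.
#' @param t requested time; the nearest grid point is used (ties toward the
#'   earlier index).
#' @return N-by-d matrix of states.
#' @export
states_at <- function(trajectories, t) {
  d <- abs(trajectories$times - t)
  idx <- which(d == min(d))[1L]
  m <- trajectories$states[, idx, , drop = FALSE]
  dim(m) <- dim(trajectories$states)[c(1L, 3L)]
  m
}
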