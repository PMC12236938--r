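## End-to-end pipeline: preprocess -> per-pair GPA -> time alignment ->
## force-matching -> integration -> inverse projection -> evaluation ->
## downstream tables, with a provenance log. Also the deterministic fixture
## generators used throughout the tests.

#' Pipeline configuration
#'
#' Every stochastic stage derives its own seed deterministically from the
#' global `seed` and the stage name, so a config + seed reproduce a run
#' exactly.
#'
#' @param series a [snapshot_series()] (programmatic use), or `NULL` when
#'   `paths`/`times` are given.
#' @param paths,times snapshot files on disk (see [load_snapshots()]).
#' @param log1p apply [log1p_normalize()] before anything else.
#' @param top_genes keep only this many highest-variance genes (`NULL` = all).
#' @param d latent dimension of the linear embedding (default 2).
#' @param holdout_times snapshot times excluded from training and used for
#'   evaluation.
#' @param gpa a [gpa_config()]; its seed is overridden per subinterval.
#' @param fm an [fm_config()].
#' @param steps_per_unit Euler steps per unit of physical time when
#'   integrating trajectories (default 200).
#' @param eps_grid entropy-regularization grid for the evaluation report.
#' @param gamma MMD kernel bandwidth.
#' @param perm_n_perm,perm_metric permutation-test settings for the per-gene
#'   comparison at held-out times (`perm_n_perm = 0` skips the table).
#' @param seed global seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(series = NULL, paths = NULL, times = NULL,
                       log1p = TRUE, top_genes = NULL, d = 2L,
                       holdout_times = numeric(0),
                       gpa = gpa_config(), fm = fm_config(),
                       steps_per_unit = 200L,
                       eps_grid = c(0.01, 0.1, 1, 10, 100), gamma = 1,
                       perm_n_perm = 200L, perm_metric = "tv",
                       seed = 1L) {
  structure(list(series = series, paths = paths, times = times,
                 log1p = log1p, top_genes = top_genes, d = as.integer(d),
                 holdout_times = holdout_times, gpa = gpa, fm = fm,
                 steps_per_unit = as.integer(steps_per_unit),
                 eps_grid = eps_grid, gamma = gamma,
                 perm_n_perm = as.integer(perm_n_perm),
                 perm_metric = perm_metric, seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full trajectory-reconstruction pipeline
#'
#' Executes preprocess -> per-pair GPA -> time alignment -> force-matching ->
#' integration -> inverse projection -> evaluation against held-out
#' snapshots (with OT-coupling and random-coupling baselines) -> per-gene
#' permutation tests, writing all artifacts into `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created; contents overwritten).
#' @return Invisibly, a list with the in-memory results: `embedding`,
#'   `field`, `trajectories` (latent `trajectory_ensemble`), `gene_dynamics`
#'   (cell x time x gene array), `evaluation` and `permutation` tables, and
#'   the artifact `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  series <- config$series
  if (is.null(series)) series <- load_snapshots(config$paths, config$times)
  bad <- setdiff(config$holdout_times, series$times)
  if (length(bad))
    stop("holdout time(s) not present in the data: ", paste(bad, collapse = ", "))
  train_idx <- which(!(series$times %in% config$holdout_times))
  if (length(train_idx) < 2L) stop("need at least 2 training time points")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log_lines <- character(0)
  stamp <- function(stage, note) {
    log_lines <<- c(log_lines, sprintf("%s\t%s", stage, note))
  }

  ## -- preprocess --
  t0 <- proc.time()[3L]
  if (config$log1p) series <- log1p_normalize(series)
  if (!is.null(config$top_genes))
    series <- select_top_variance_genes(series, config$top_genes)
  train_series <- snapshot_series(series$matrices[train_idx],
                                  series$times[train_idx],
                                  gene_names = series$gene_names)
  fit <- fit_latent(train_series, config$d)
  emb <- fit$embedding
  latent_train <- fit$latent
  paths$embedding <- save_embedding(emb, file.path(out_dir, "embedding.json"))
  stamp("preprocess", sprintf("genes=%d d=%d elapsed=%.1fs",
                              length(series$gene_names), config$d,
                              proc.time()[3L] - t0))

  ## -- per-pair GPA --
  t0 <- proc.time()[3L]
  tr_times <- series$times[train_idx]
  gpa_runs <- vector("list", length(train_idx) - 1L)
  for (i in seq_along(gpa_runs)) {
    cfg <- config$gpa
    cfg$seed <- stage_seed(config$seed, paste0("gpa", i))
    # horizon guard: with transport speed bounded by L, the reachable
    # distance is max_iters * dt * L; keep it at least 4x the centroid
    # displacement of this snapshot pair so the flow can both travel and
    # settle within budget
    dist <- sqrt(sum((colMeans(latent_train[[i + 1L]]) -
                        colMeans(latent_train[[i]]))^2))
    cfg$dt <- max(cfg$dt, 4 * dist / (cfg$L * cfg$max_iters))
    gpa_runs[[i]] <- run_gpa(latent_train[[i]], latent_train[[i + 1L]],
                             cfg, subinterval_id = i)
  }
  stamp("gpa", sprintf("subintervals=%d records=%d elapsed=%.1fs",
                       length(gpa_runs),
                       sum(vapply(gpa_runs, function(r) nrow(r$velocities), 1L)),
                       proc.time()[3L] - t0))

  ## -- force-matching --
  t0 <- proc.time()[3L]
  samples <- align_times(gpa_runs, tr_times)
  fm_cfg <- config$fm
  fm_cfg$seed <- stage_seed(config$seed, "force_matching")
  field <- train_velocity_field(samples, fm_cfg)
  stamp("force_matching", sprintf("samples=%d train_loss=%.4g elapsed=%.1fs",
                                  nrow(samples), field$train_loss,
                                  proc.time()[3L] - t0))

  ## -- integration + inverse projection --
  t0 <- proc.time()[3L]
  span <- diff(range(tr_times))
  n_steps <- max(1L, as.integer(ceiling(config$steps_per_unit * span)))
  traj <- integrate_trajectories(field, latent_train[[1L]],
                                 min(tr_times), max(tr_times), n_steps)
  gene_dyn <- inverse_project(traj$states, emb)
  d <- emb$d
  N <- dim(traj$states)[1L]
  thin <- unique(round(seq(1L, length(traj$times),
                           length.out = min(101L, length(traj$times)))))
  traj_tab <- do.call(rbind, lapply(thin, function(m)
    data.frame(cell_id = seq_len(N), s = traj$times[m],
               matrix(traj$states[, m, ], N, d,
                      dimnames = list(NULL, paste0("x", seq_len(d)))))))
  paths$trajectories <- .write_tsv(
    format(traj_tab, digits = 10, trim = TRUE),
    file.path(out_dir, "trajectories.tsv"))
  gene_tab <- do.call(rbind, lapply(thin, function(m)
    cbind(data.frame(cell_id = seq_len(N), s = traj$times[m]),
          as.data.frame(gene_dyn[, m, ]))))
  paths$gene_dynamics <- .write_tsv(
    format(gene_tab, digits = 8, trim = TRUE),
    file.path(out_dir, "gene_dynamics.tsv"))
  stamp("integrate", sprintf("steps=%d elapsed=%.1fs", n_steps,
                             proc.time()[3L] - t0))

  ## -- evaluation at held-out times --
  evaluation <- NULL
  perm_tab <- NULL
  if (length(config$holdout_times)) {
    t0 <- proc.time()[3L]
    eval_rows <- list()
    perm_rows <- list()
    for (ht in config$holdout_times) {
      obs_latent <- project_latent(series$matrices[[which(series$times == ht)]], emb)
      lo <- max(tr_times[tr_times < ht]); hi <- min(tr_times[tr_times > ht])
      frac <- (ht - lo) / (hi - lo)
      src <- latent_train[[which(tr_times == lo)]]
      tgt <- latent_train[[which(tr_times == hi)]]
      # equal-information protocol: the coupling baselines interpolate
      # between the flanking training snapshots, so the field-based
      # prediction also starts from the last training snapshot before the
      # held-out time and integrates forward to it
      pred_traj <- integrate_trajectories(
        field, src, lo, ht,
        max(1L, as.integer(ceiling(config$steps_per_unit * (ht - lo)))))
      pred <- states_at(pred_traj, ht)
      preds <- list(
        profet = pred,
        ot_baseline = ot_coupling_interpolate(src, tgt, frac),
        random_baseline = random_coupling_interpolate(
          src, tgt, frac, seed = stage_seed(config$seed, paste0("rc", ht)),
          size = 3L * nrow(src)))
      eval_rows[[length(eval_rows) + 1L]] <-
        evaluation_report(preds, obs_latent, config$eps_grid, config$gamma,
                          time = ht)
      if (config$perm_n_perm > 0L) {
        obs_expr <- series$matrices[[which(series$times == ht)]]
        pred_expr <- inverse_project(pred, emb)
        for (g in seq_along(series$gene_names)) {
          pt <- permutation_test(pred_expr[, g], obs_expr[, g],
                                 metric = config$perm_metric,
                                 n_perm = config$perm_n_perm,
                                 seed = stage_seed(config$seed,
                                                   paste0("perm", ht, "_", g)),
                                 gene = series$gene_names[g])
          perm_rows[[length(perm_rows) + 1L]] <-
            data.frame(time = ht, gene = pt$gene, metric = pt$metric,
                       observed = pt$observed, p_value = pt$p_value)
        }
      }
    }
    evaluation <- do.call(rbind, eval_rows)
    paths$evaluation <- .write_tsv(evaluation,
                                   file.path(out_dir, "evaluation.tsv"))
    if (length(perm_rows)) {
      perm_tab <- do.call(rbind, perm_rows)
      paths$permutation <- .write_tsv(perm_tab,
                                      file.path(out_dir, "permutation_tests.tsv"))
    }
    stamp("evaluate", sprintf("holdouts=%d elapsed=%.1fs",
                              length(config$holdout_times),
                              proc.time()[3L] - t0))
  }

  ## -- provenance --
  cfg_path <- file.path(out_dir, "config.json")
  cfg_ser <- config
  cfg_ser$series <- if (is.null(config$series)) NULL else "<in-memory series>"
  jsonlite::write_json(lapply(cfg_ser, function(x)
    if (is.list(x)) unclass(x) else x), cfg_path, digits = NA,
    auto_unbox = TRUE, null = "null", force = TRUE)
  prov <- c(sprintf("package_version\t%s",
                    as.character(utils::packageVersion("profet"))),
            sprintf("config_md5\t%s", unname(tools::md5sum(cfg_path))),
            sprintf("global_seed\t%d", config$seed),
            log_lines)
  writeLines(prov, file.path(out_dir, "provenance.log"))
  paths$config <- cfg_path

  invisible(list(embedding = emb, field = field, trajectories = traj,
                 gene_dynamics = gene_dyn, evaluation = evaluation,
                 permutation = perm_tab, gpa_runs = gpa_runs, paths = paths))
}

#' Simulate the packaged EMT network as a snapshot series
#'
#' Draws an ensemble of kinetic parameterizations of the packaged 26-gene
#' EMT-like topology (one parameter set and one uniform random initial
#' condition in `[0, g/k]` per replicate), integrates the stochastic dynamics
#' by Euler-Maruyama, and subsamples snapshots at the requested times.
#'
#' @param n_rep number of replicate trajectories (cells per snapshot).
#' @param sample_times snapshot times (default 0:4).
#' @param dt integration step (default 0.01).
#' @param seed integer seed.
#' @param D noise magnitude (default 1).
#' @param J optional topology; defaults to the packaged synthetic EMT matrix.
#' @return A [snapshot_series()].
#' @export
simulate_emt_series <- function(n_rep = 500L, sample_times = 0:4, dt = 0.01,
                                seed = 1L, D = 1, J = NULL) {
  if (is.null(J))
    J <- read_grn_topology(system.file("extdata", "emt_grn_26_synthetic.txt",
                                       package = "profet"))
  models <- sample_grn_ensemble(J, n_rep, seed = stage_seed(seed, "ensemble"),
                                D = D)
  G <- nrow(J)
  t_end <- max(sample_times)
  n_steps <- round(t_end / dt)
  # stack per-replicate kinetics so each Euler-Maruyama step is vectorized
  # across the whole ensemble
  gmat <- t(vapply(models, `[[`, numeric(G), "g"))
  kmat <- t(vapply(models, `[[`, numeric(G), "k"))
  edges <- which(J != 0, arr.ind = TRUE)
  lamE <- vapply(models, function(m) m$lam[edges], numeric(nrow(edges)))
  thetaE <- vapply(models, function(m) m$theta[edges], numeric(nrow(edges)))
  nE <- vapply(models, function(m) m$n[edges], numeric(nrow(edges)))
  set.seed(stage_seed(seed, "init"))
  X <- matrix(stats::runif(n_rep * G), n_rep, G) * gmat / kmat
  vals <- array(NA_real_, dim = c(n_rep, n_steps + 1L, G),
                dimnames = list(NULL, NULL, rownames(J)))
  vals[, 1L, ] <- X
  set.seed(stage_seed(seed, "noise"))
  sq <- sqrt(dt)
  for (m in seq_len(n_steps)) {
    prodHS <- matrix(1, n_rep, G)
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1L]; j <- edges[e, 2L]
      prodHS[, i] <- prodHS[, i] *
        shifted_hill(X[, j], lamE[e, ], thetaE[e, ], nE[e, ])
    }
    drift <- gmat * prodHS - kmat * X
    Xn <- X + dt * drift
    if (D > 0) Xn <- Xn + D * X * sq * matrix(stats::rnorm(n_rep * G), n_rep, G)
    Xn[Xn < 0] <- 0
    X <- Xn
    vals[, m + 1L, ] <- X
  }
  traj <- structure(list(times = seq(0, by = dt, length.out = n_steps + 1L),
                         values = vals, seed = seed, genes = rownames(J)),
                    class = "grn_trajectories")
  subsample_snapshots(traj, sample_times)
}

#' Generate a deterministic test dataset on disk
#'
#' Three fixture kinds used across examples and tests:
#' `"emt-grn"` -- the synthetic EMT time course (5 snapshots of `n_rep` cells
#' by 26 genes, plus manifest); `"gaussian-shift"` -- three 1-D snapshots
#' N(0,1) -> N(3,1) -> N(0,1) of 200 cells each; `"trimodal-shift"` -- a
#' per-cell table of pre/post states whose displacements form a balanced
#' three-component mixture (modes 1, 5, 9, sd 0.3, n = 600).
#'
#' @param kind fixture name.
#' @param seed integer seed; the same seed yields identical files.
#' @param dir output directory.
#' @param n_rep replicates for the EMT fixture (default 500).
#' @return Invisibly, the main file written (manifest or table path).
#' @export
make_fixture <- function(kind = c("emt-grn", "gaussian-shift", "trimodal-shift"),
                         seed = 0L, dir, n_rep = 500L) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "emt-grn") {
    series <- simulate_emt_series(n_rep = n_rep, seed = seed)
    return(invisible(write_snapshots(series, dir, prefix = "emt")))
  }
  if (kind == "gaussian-shift") {
    set.seed(stage_seed(seed, "gaussian-shift"))
    mats <- lapply(c(0, 3, 0), function(mu)
      matrix(stats::rnorm(200, mean = mu), ncol = 1L,
             dimnames = list(NULL, "g1")))
    series <- snapshot_series(mats, times = c(0, 1, 2))
    return(invisible(write_snapshots(series, dir, prefix = "gaussian")))
  }
  set.seed(stage_seed(seed, "trimodal-shift"))
  comp <- rep(1:3, each = 200L)
  disp <- stats::rnorm(600, mean = c(1, 5, 9)[comp], sd = 0.3)
  tab <- data.frame(cell_id = seq_len(600L), component = comp,
                    x_pre = 0, x_post = disp)
  path <- file.path(dir, "trimodal_shift.tsv")
  .write_tsv(format(tab, digits = 15, trim = TRUE), path)
  invisible(path)
}

#' Build a trajectory ensemble from a pre/post state table
#'
#' Helper for displacement analyses on two-column (pre, post) data such as
#' the `"trimodal-shift"` fixture: linear paths from `x_pre` to `x_post` on
#' `[0, 1]`.
#'
#' @param tab data.frame with `x_pre` and `x_post` columns.
#' @return A `trajectory_ensemble` with times `c(0, 1)`.
#' @export
trajectories_from_endpoints <- function(tab) {
  states <- array(NA_real_, dim = c(nrow(tab), 2L, 1L))
  states[, 1L, 1L] <- tab$x_pre
  states[, 2L, 1L] <- tab$x_post
  structure(list(times = c(0, 1), states = states),
            class = "trajectory_ensemble")
}
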