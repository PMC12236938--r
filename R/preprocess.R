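## Snapshot container, normalization, high-variance gene selection and the
## linear latent embedding (covariance PCA) shared by all downstream stages.

#' Construct a time-stamped snapshot series
#'
#' The method's universal input: an ordered collection of cells-by-genes
#' expression matrices, one per observation time, over a shared gene list.
#'
#' @param matrices list of non-negative cells-by-genes matrices sharing gene
#'   count and order.
#' @param times strictly increasing numeric time stamps, one per matrix.
#' @param gene_names shared ordered gene list; defaults to the column names of
#'   the first matrix.
#' @param cell_ids optional list of per-matrix cell identifier vectors.
#' @return An object of class `snapshot_series`.
#' @export
snapshot_series <- function(matrices, times, gene_names = NULL, cell_ids = NULL) {
  if (length(matrices) != length(times)) stop("one matrix per time stamp required")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  matrices <- lapply(matrices, as.matrix)
  G <- ncol(matrices[[1L]])
  if (!all(vapply(matrices, ncol, 1L) == G))
    stop("all matrices must share the same gene count")
  if (is.null(gene_names)) gene_names <- colnames(matrices[[1L]])
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(G))
  if (length(gene_names) != G) stop("gene_names length must match gene count")
  matrices <- lapply(matrices, function(m) { colnames(m) <- gene_names; m })
  if (is.null(cell_ids))
    cell_ids <- lapply(seq_along(matrices), function(i)
      paste0("t", i, "_c", seq_len(nrow(matrices[[i]]))))
  structure(list(matrices = matrices, times = as.numeric(times),
                 gene_names = gene_names, cell_ids = cell_ids),
            class = "snapshot_series")
}

#' @exportS3Method base::print
print.snapshot_series <- function(x, ...) {
  cat(sprintf("snapshot_series: %d time points, %d genes; cells per time: %s\n",
              length(x$times), length(x$gene_names),
              paste(vapply(x$matrices, nrow, 1L), collapse = ", ")))
  invisible(x)
}

n_snapshots <- function(series) length(series$times)

#' Log-transform expression values
#'
#' Replaces each value `x` with `log(1 + x)`; monotone and zero-preserving.
#'
#' @param x a non-negative matrix or a `snapshot_series` (transformed
#'   matrix-wise).
#' @return Same shape/class as the input.
#' @export
log1p_normalize <- function(x) {
  if (inherits(x, "snapshot_series")) {
    x$matrices <- lapply(x$matrices, log1p_normalize)
    return(x)
  }
  if (any(x < 0)) stop("expression values must be non-negative")
  log1p(x)
}

#' Select the genes with the highest pooled variance
#'
#' Variance is computed per gene across all cells pooled over time points
#' (sample variance, 1/(N-1) divisor). The original gene order is preserved
#' among the selected genes; ties at the cut keep the lower gene index.
#'
#' @param series a [snapshot_series()], typically after [log1p_normalize()].
#' @param k number of genes to keep, `1 <= k <= gene count`.
#' @return The series restricted to `k` genes.
#' @export
select_top_variance_genes <- function(series, k) {
  G <- length(series$gene_names)
  if (k < 1 || k > G) stop("k must lie in [1, gene count]")
  pooled <- do.call(rbind, series$matrices)
  v <- apply(pooled, 2L, stats::var)
  keep <- sort(order(v, seq_len(G), decreasing = c(TRUE, FALSE),
                     method = "radix")[seq_len(k)])
  series$matrices <- lapply(series$matrices, function(m) m[, keep, drop = FALSE])
  series$gene_names <- series$gene_names[keep]
  series
}

#' Fit the linear latent embedding and project a snapshot series
#'
#' Pools all time points into one matrix and fits covariance PCA (genes
#' centered, not scaled). For reproducibility the sign of each loading column
#' is fixed so that its largest-magnitude entry is positive.
#'
#' @param series a [snapshot_series()].
#' @param d latent dimension, `d <= min(total cells, genes)`.
#' @return List with `embedding` (class `latent_embedding`: `loadings`
#'   genes-by-d with orthonormal columns, `center`, `explained_variance_ratio`,
#'   `d`) and `latent`, a list of cells-by-d latent coordinate matrices
#'   parallel to the input series.
#' @export
fit_latent <- function(series, d) {
  pooled <- do.call(rbind, series$matrices)
  if (d < 1 || d > min(nrow(pooled), ncol(pooled)))
    stop("latent dimension d out of range")
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  L <- pc$rotation[, seq_len(d), drop = FALSE]
  flip <- apply(L, 2L, function(col) sign(col[which.max(abs(col))]))
  L <- sweep(L, 2L, flip, "*")
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  emb <- structure(list(loadings = L, center = pc$center,
                        explained_variance_ratio = evr[seq_len(d)], d = d,
                        gene_names = series$gene_names),
                   class = "latent_embedding")
  list(embedding = emb, latent = lapply(series$matrices, project_latent, embedding = emb))
}

#' @exportS3Method base::print
print.latent_embedding <- function(x, ...) {
  cat(sprintf("latent_embedding: %d genes -> %d dims; explained variance %.1f%%\n",
              nrow(x$loadings), x$d, 100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project expression values into the latent space
#'
#' @param x cells-by-genes matrix (or vector of one cell).
#' @param embedding a fitted `latent_embedding`.
#' @return Cells-by-d latent coordinates `(x - center) %*% loadings`.
#' @export
project_latent <- function(x, embedding) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != nrow(embedding$loadings)) stop("gene dimension mismatch")
  sweep(X, 2L, embedding$center, "-") %*% embedding$loadings
}

#' Reconstruct gene-space values from latent coordinates
#'
#' The inverse of the linear projection: `latent %*% t(loadings) + center`,
#' applied row-wise; along trajectories this yields per-gene, per-cell time
#' series.
#'
#' @param latent cells-by-d matrix (or a cell x time x d array, inverted
#'   pointwise).
#' @param embedding a fitted `latent_embedding`.
#' @return Gene-space values with gene names as column names.
#' @export
inverse_project <- function(latent, embedding) {
  if (length(dim(latent)) == 3L) {
    dm <- dim(latent)
    flat <- matrix(latent, nrow = dm[1L] * dm[2L], ncol = dm[3L])
    rec <- inverse_project(flat, embedding)
    return(array(rec, dim = c(dm[1L], dm[2L], ncol(rec)),
                 dimnames = list(NULL, NULL, embedding$gene_names)))
  }
  X <- if (is.null(dim(latent))) matrix(latent, nrow = 1L) else as.matrix(latent)
  if (ncol(X) != embedding$d) stop("latent dimension mismatch")
  out <- sweep(tcrossprod(X, embedding$loadings), 2L, embedding$center, "+")
  colnames(out) <- embedding$gene_names
  out
}
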