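## File I/O: snapshot matrices as delimited text or MatrixMarket triplets,
## manifests, embedding archives, configs. Expression on disk is always
## cells x genes with a gene-name header.

#' Read one expression matrix
#'
#' Delimited text (cells x genes, header row of gene names, optional first
#' column of cell ids) or MatrixMarket (`.mtx` with `<prefix>_genes.txt` /
#' `<prefix>_barcodes.txt` sidecars).
#'
#' @param path file path; format inferred from the `.mtx` extension.
#' @return Numeric matrix with gene column names and cell row names.
#' @export
read_snapshot_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    prefix <- sub("\\.mtx$", "", path)
    gf <- paste0(prefix, "_genes.txt")
    bf <- paste0(prefix, "_barcodes.txt")
    if (!file.exists(gf)) stop("missing gene sidecar: ", gf)
    genes <- readLines(gf)
    if (length(genes) == ncol(m) ) colnames(m) <- genes
    else if (length(genes) == nrow(m)) { m <- t(m); colnames(m) <- genes }
    else stop("gene sidecar length matches neither matrix dimension")
    if (file.exists(bf)) rownames(m) <- readLines(bf)
    return(m)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "", check.names = FALSE)
  if (ncol(tab) > 1L && !is.numeric(tab[[1L]])) {
    rn <- tab[[1L]]
    tab <- tab[, -1L, drop = FALSE]
    m <- as.matrix(tab); rownames(m) <- rn
  } else m <- as.matrix(tab)
  storage.mode(m) <- "double"
  m
}

#' Load a time-stamped snapshot series from disk
#'
#' Either a manifest file (two whitespace-delimited columns `file` and
#' `time`, paths relative to the manifest) or explicit `paths` + `times`.
#' Gene headers are aligned by name across files; in the default lenient
#' mode mismatched gene sets are intersected with a warning, in strict mode
#' any inconsistency is an error.
#'
#' @param paths manifest path (single string, `times = NULL`) or a vector of
#'   matrix paths.
#' @param times snapshot time stamps, one per path.
#' @param strict error (instead of warn + intersect) on gene-set mismatch.
#' @return A [snapshot_series()].
#' @export
load_snapshots <- function(paths, times = NULL, strict = FALSE) {
  if (length(paths) == 1L && is.null(times)) {
    man <- utils::read.table(paths, header = TRUE, sep = "",
                             stringsAsFactors = FALSE)
    if (!all(c("file", "time") %in% names(man)))
      stop("manifest needs 'file' and 'time' columns")
    base <- dirname(paths)
    paths <- file.path(base, man$file)
    times <- man$time
  }
  if (length(paths) != length(times)) stop("one time per file required")
  ord <- order(times)
  paths <- paths[ord]; times <- times[ord]
  mats <- lapply(paths, read_snapshot_matrix)
  gene_sets <- lapply(mats, colnames)
  if (any(vapply(gene_sets, is.null, TRUE)))
    stop("every matrix needs a gene-name header")
  ref <- gene_sets[[1L]]
  shared <- Reduce(intersect, gene_sets)
  if (!all(lengths(gene_sets) == length(shared))) {
    if (strict) stop("gene sets differ across snapshot files (strict mode)")
    warning(sprintf("gene sets differ across files; using the %d shared genes",
                    length(shared)))
  }
  shared <- ref[ref %in% shared]  # keep first file's order
  mats <- lapply(mats, function(m) m[, shared, drop = FALSE])
  snapshot_series(mats, times = times, gene_names = shared,
                  cell_ids = lapply(mats, rownames))
}

#' Write a snapshot series to a directory
#'
#' One tab-delimited cells-by-genes matrix per time point, a `manifest.tsv`
#' listing files and time stamps, and a `combined.tsv` with a `time` column.
#'
#' @param series a [snapshot_series()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the manifest path.
#' @export
write_snapshots <- function(series, dir, prefix = "snapshot") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(n_snapshots(series))
  for (i in seq_len(n_snapshots(series))) {
    files[i] <- sprintf("%s_t%g.tsv", prefix, series$times[i])
    m <- series$matrices[[i]]
    utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                       file.path(dir, files[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(data.frame(file = files, time = series$times), man,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comb <- do.call(rbind, lapply(seq_along(series$matrices), function(i)
    cbind(data.frame(time = series$times[i]),
          as.data.frame(series$matrices[[i]]))))
  utils::write.table(comb, file.path(dir, paste0(prefix, "_combined.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' Serialize / restore a latent embedding
#'
#' The embedding (loadings, center, explained-variance ratios, gene names) is
#' stored as a single JSON archive for reuse by downstream stages.
#'
#' @param embedding a `latent_embedding`.
#' @param path archive path (`.json`).
#' @return `save_embedding` invisibly returns `path`; `load_embedding`
#'   returns the `latent_embedding`.
#' @export
save_embedding <- function(embedding, path) {
  obj <- list(loadings = unclass(embedding$loadings),
              center = embedding$center,
              explained_variance_ratio = embedding$explained_variance_ratio,
              d = embedding$d, gene_names = embedding$gene_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(obj$loadings)
  structure(list(loadings = L, center = as.numeric(obj$center),
                 explained_variance_ratio = as.numeric(obj$explained_variance_ratio),
                 d = as.integer(obj$d), gene_names = obj$gene_names),
            class = "latent_embedding")
}

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
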