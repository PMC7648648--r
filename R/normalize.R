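## Normalization, variable-gene selection, PCA embedding, centroid batch
## correction and pseudobulk replicate agreement.

#' Log counts-per-10k normalization
#'
#' Transforms each count to `ln(1 + count / total_umi * scale_factor)`
#' (CP10K with the default scale factor 1e4). Zeros map to zeros so the
#' sparsity pattern is preserved; within a cell the transform is monotone
#' in the raw count.
#'
#' @param counts genes x cells count matrix; every cell must have
#'   `total_umi > 0` (run QC first).
#' @param scale_factor counts-per-total scaling constant (default 1e4).
#' @return Sparse normalized matrix of the same shape.
#' @export
normalize_log_cp10k <- function(counts, scale_factor = 1e4) {
  if (scale_factor <= 0) stop("scale_factor must be > 0")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    stop("cells with zero total UMI present; filter them with filter_cells() first")
  }
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  fac <- scale_factor / tot
  ## operate on the non-zero slots only: column of each slot via pointer diff
  j <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * fac[j])
  m
}

#' Select highly variable genes
#'
#' Ranks genes by standardized dispersion: variance/mean of the normalized
#' values, z-scored within 20 equal-frequency mean-expression bins, so
#' highly expressed genes do not dominate. Deterministic with a
#' lexicographic tie-break on the gene identifier.
#'
#' @param norm normalized genes x cells matrix.
#' @param n number of genes to return (`1 <= n <= n_genes`).
#' @param n_bins mean-expression bins for dispersion standardization.
#' @return Character vector of `n` gene identifiers, most variable first.
#' @export
select_variable_genes <- function(norm, n = 2000, n_bins = 20) {
  if (n <= 0) stop("n must be positive")
  if (n > nrow(norm)) stop("n exceeds the number of genes")
  st <- .row_stats(norm)
  disp <- ifelse(st$mean > 0, st$var / st$mean, 0)
  br <- unique(stats::quantile(st$mean, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(st$mean, breaks = br, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  g <- rownames(norm)
  g[order(-z, g)][seq_len(n)]
}

#' PCA embedding of selected genes
#'
#' Cells are embedded on principal-component scores of the gene-standardized
#' (centered, unit variance, clipped at +/- `clip`) submatrix. The sign of
#' each component is fixed so that its largest-magnitude gene loading is
#' positive, making the embedding deterministic.
#'
#' @param norm normalized genes x cells matrix.
#' @param genes genes to use (e.g. from [select_variable_genes()]).
#' @param n_components number of components,
#'   `<= min(n_cells, length(genes))`.
#' @param clip standardized values are clipped at +/- `clip`.
#' @return An `embedding`: list with `coords` (cells x k score matrix),
#'   `var_share` (non-increasing variance shares), `loadings`, `genes`.
#' @export
embed_pca <- function(norm, genes, n_components = 30, clip = 10) {
  .check_genes_present(genes, rownames(norm))
  if (n_components > min(ncol(norm), length(genes))) {
    stop("n_components exceeds min(n_cells, n_genes)")
  }
  x <- t(.as_dense(norm[genes, , drop = FALSE]))  # cells x genes
  x <- scale(x)
  x[is.na(x)] <- 0
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    w <- pc$rotation[, k]
    sign(w[which.max(abs(w))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  coords <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(coords) <- colnames(norm)
  structure(list(coords = coords,
                 var_share = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
                 eig = pc$sdev^2,
                 n_cells = ncol(norm),
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 genes = genes),
            class = "embedding")
}

#' @method print embedding
#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("PCA embedding: %d cells x %d components (%d genes)\n",
              nrow(x$coords), ncol(x$coords), length(x$genes)))
  invisible(x)
}

#' Centroid batch correction in embedding space
#'
#' Translates each batch so its centroid coincides with the global centroid;
#' within-batch geometry is preserved exactly. This removes the additive
#' component that per-gene multiplicative batch noise induces in PCA space.
#' Batches with a single cell are left uncorrected with a warning.
#'
#' @param emb an [embed_pca()] embedding.
#' @param batches per-cell batch labels (length `n_cells`).
#' @return The corrected `embedding`.
#' @export
correct_batches <- function(emb, batches) {
  stopifnot(inherits(emb, "embedding"))
  if (length(batches) != nrow(emb$coords)) {
    stop("batches must have one label per cell")
  }
  if (length(unique(batches)) < 2L) stop("at least two batches are required")
  global <- colMeans(emb$coords)
  for (b in unique(batches)) {
    i <- which(batches == b)
    if (length(i) < 2L) {
      warning(sprintf("batch '%s' has a single cell; left uncorrected", b))
      next
    }
    shift <- global - colMeans(emb$coords[i, , drop = FALSE])
    emb$coords[i, ] <- sweep(emb$coords[i, , drop = FALSE], 2, shift, "+")
  }
  emb
}

#' Pseudobulk replicate agreement
#'
#' Averages normalized expression per gene within each batch and returns
#' the squared Pearson correlation for every batch pair — the replicate
#' concordance check (well-matched replicates give r^2 close to 1).
#'
#' @param norm normalized genes x cells matrix.
#' @param batches per-cell batch labels.
#' @return Symmetric batch x batch matrix of r^2 with unit diagonal.
#' @export
pseudobulk_correlation <- function(norm, batches) {
  if (length(batches) != ncol(norm)) stop("batches must have one label per cell")
  ub <- sort(unique(batches))
  if (length(ub) < 2L) stop("at least two batches are required")
  prof <- vapply(ub, function(b) {
    i <- which(batches == b)
    if (!length(i)) stop(sprintf("batch '%s' has zero cells", b))
    Matrix::rowMeans(norm[, i, drop = FALSE])
  }, numeric(nrow(norm)))
  r2 <- stats::cor(prof)^2
  dimnames(r2) <- list(ub, ub)
  diag(r2) <- 1
  r2
}
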