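## Marker ranking, unique-gene tables, dot-plot summaries, reference-based
## cluster annotation and gene-set scoring.

#' Rank marker genes of one cluster
#'
#' Tests every gene of the cluster against all other cells with a two-sided
#' Wilcoxon rank-sum test (BH adjustment across genes), with fold changes
#' computed on expm1-scale means. Results are sorted by adjusted p, then by
#' decreasing |log2FC|.
#'
#' @param norm normalized genes x cells matrix.
#' @param labels per-cell cluster labels.
#' @param cluster the cluster to characterise (>= 3 cells).
#' @return data.frame of marker records: gene, cluster, log2_fold_change,
#'   p_value, p_adjusted, frac_in, frac_out, uniqueness (margin between the
#'   in-cluster mean and the maximum mean among the other clusters, in
#'   normalized units).
#' @export
rank_markers <- function(norm, labels, cluster) {
  stopifnot(length(labels) == ncol(norm))
  grp <- labels == cluster
  if (sum(grp) < 3L) {
    stop("cluster has fewer than 3 cells; annotate it by supervised marker expression instead")
  }
  x <- .as_dense(norm)
  ts <- .rank_sum(x, grp)
  padj <- stats::p.adjust(ts$p_value, method = "BH")
  mean_in <- rowMeans(expm1(x[, grp, drop = FALSE]))
  mean_out <- rowMeans(expm1(x[, !grp, drop = FALSE]))
  ## all-zero genes: no evidence either way
  allzero <- mean_in == 0 & mean_out == 0
  pv <- ts$p_value
  pv[allzero] <- 1
  padj[allzero] <- 1
  prof <- .cluster_means(norm, labels)
  others <- setdiff(colnames(prof), as.character(cluster))
  max_other <- if (length(others)) {
    apply(prof[, others, drop = FALSE], 1, max)
  } else {
    rep(0, nrow(prof))
  }
  out <- data.frame(
    gene = rownames(norm),
    cluster = cluster,
    log2_fold_change = .log2_fc(mean_in, mean_out),
    p_value = pv,
    p_adjusted = padj,
    frac_in = rowMeans(x[, grp, drop = FALSE] > 0),
    frac_out = rowMeans(x[, !grp, drop = FALSE] > 0),
    uniqueness = prof[, as.character(cluster)] - max_other,
    stringsAsFactors = FALSE)
  out[order(out$p_adjusted, -abs(out$log2_fold_change), out$gene), ]
}

## per-cluster mean normalized expression, genes x clusters
.cluster_means <- function(norm, labels) {
  levs <- sort(unique(as.character(labels)))
  prof <- vapply(levs, function(lv) {
    Matrix::rowMeans(norm[, labels == lv, drop = FALSE])
  }, numeric(nrow(norm)))
  dimnames(prof) <- list(rownames(norm), levs)
  prof
}

#' Top unique genes per cluster
#'
#' Ranks genes by a uniqueness margin — the in-cluster mean normalized
#' expression minus the maximum mean among all other clusters — and
#' assigns each gene to the single cluster where that margin is largest,
#' so a gene appears in at most one cluster's list. Ties break
#' lexicographically on the gene id.
#'
#' @param norm normalized genes x cells matrix.
#' @param labels per-cell cluster labels (>= 2 clusters).
#' @param N list length per cluster.
#' @return Named list: cluster -> ordered character vector of <= N genes.
#' @export
top_unique_genes <- function(norm, labels, N = 10) {
  if (N <= 0) stop("N must be positive")
  levs <- sort(unique(as.character(labels)))
  if (length(levs) < 2L) stop("at least two clusters are required")
  prof <- .cluster_means(norm, labels)
  best <- max.col(prof, ties.method = "first")
  margin <- vapply(seq_len(nrow(prof)), function(g) {
    prof[g, best[g]] - max(prof[g, -best[g]])
  }, numeric(1))
  out <- lapply(seq_along(levs), function(k) {
    i <- which(best == k)
    i <- i[order(-margin[i], rownames(prof)[i])]
    rownames(prof)[utils::head(i, N)]
  })
  names(out) <- levs
  out
}

#' Dot-plot summary statistics
#'
#' @param norm normalized genes x cells matrix.
#' @param labels per-cell cluster labels.
#' @param genes genes to summarise.
#' @return data.frame (cluster x gene long form): `cluster`, `gene`,
#'   `frac_expressing` (share of cells with value > 0) and
#'   `mean_expression` (mean over all cells of the cluster).
#' @export
dot_plot_stats <- function(norm, labels, genes) {
  .check_genes_present(genes, rownames(norm))
  levs <- sort(unique(as.character(labels)))
  rows <- lapply(levs, function(lv) {
    sub <- norm[genes, labels == lv, drop = FALSE]
    data.frame(cluster = lv, gene = genes,
               frac_expressing = Matrix::rowSums(sub > 0) / ncol(sub),
               mean_expression = Matrix::rowMeans(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate clusters against a marker reference
#'
#' Scores each cluster for each reference cell type as the mean z-scored
#' expression (z across cluster means, per gene) of the type's "+" genes
#' minus the mean of its "-" genes, and assigns the best-scoring type when
#' its margin over the runner-up reaches `min_margin`.
#'
#' @param norm normalized genes x cells matrix.
#' @param labels per-cell cluster labels.
#' @param reference data.frame with columns `cell_type`, `gene`, `sign`
#'   ("+" or "-").
#' @param min_margin required margin over the runner-up type; clusters
#'   below it (or any cluster when `min_margin` is infinite) are
#'   "unassigned".
#' @return data.frame: cluster, cell_type, score, margin.
#' @export
annotate_clusters <- function(norm, labels, reference, min_margin = 0) {
  reference <- as.data.frame(reference, stringsAsFactors = FALSE)
  if (!nrow(reference)) stop("empty marker reference")
  stopifnot(all(c("cell_type", "gene", "sign") %in% names(reference)))
  if (!all(reference$sign %in% c("+", "-"))) stop("signs must be '+' or '-'")
  .check_genes_present(unique(reference$gene), rownames(norm), "reference gene")
  prof <- .cluster_means(norm, labels)
  z <- t(scale(t(prof)))
  z[is.na(z)] <- 0
  types <- unique(reference$cell_type)
  scores <- vapply(types, function(ty) {
    r <- reference[reference$cell_type == ty, ]
    pos <- r$gene[r$sign == "+"]
    neg <- r$gene[r$sign == "-"]
    s <- if (length(pos)) colMeans(z[pos, , drop = FALSE]) else
      rep(0, ncol(z))
    if (length(neg)) s <- s - colMeans(z[neg, , drop = FALSE])
    s
  }, numeric(ncol(prof)))
  scores <- matrix(scores, nrow = ncol(prof),
                   dimnames = list(colnames(prof), types))
  out <- lapply(rownames(scores), function(cl) {
    s <- stats::setNames(as.numeric(scores[cl, ]), colnames(scores))
    best <- which.max(s)
    runner <- if (length(s) > 1L) max(s[-best]) else -Inf
    margin <- s[best] - runner
    assigned <- is.finite(min_margin) && margin >= min_margin
    data.frame(cluster = cl,
               cell_type = if (assigned) names(s)[best] else "unassigned",
               score = unname(s[best]), margin = margin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Expression-matched gene-set score
#'
#' Per-cell score of a gene set relative to expression-matched controls:
#' mean normalized expression of the set genes minus the mean of control
#' genes drawn, for each set gene, from the same average-expression bin
#' (so depth and baseline expression do not masquerade as signal).
#'
#' @param norm normalized genes x cells matrix.
#' @param gene_set character vector of gene ids (duplicates are dropped
#'   with a warning; at least one must be present in the matrix).
#' @param n_control_bins average-expression bins controls are drawn from.
#' @param n_controls control genes sampled per set gene.
#' @param seed integer seed for control sampling.
#' @return Named numeric vector: one score per cell.
#' @export
score_gene_set <- function(norm, gene_set, n_control_bins = 25,
                           n_controls = 100, seed = 1L) {
  if (anyDuplicated(gene_set)) {
    warning("duplicated genes in gene_set; deduplicating")
    gene_set <- unique(gene_set)
  }
  present <- intersect(gene_set, rownames(norm))
  if (!length(present)) {
    stop("no gene of the set is present in the matrix; missing: ",
         paste(utils::head(gene_set, 10), collapse = ", "))
  }
  avg <- Matrix::rowMeans(norm)
  br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_control_bins + 1)))
  bin <- cut(avg, breaks = br, include.lowest = TRUE)
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- which(bin == bin[match(g, rownames(norm))])
    rownames(norm)[sample(pool, min(n_controls, length(pool)))]
  }))
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(set_mean - ctrl_mean), colnames(norm))
}
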