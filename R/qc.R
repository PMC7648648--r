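## Cell-level quality control: UMI/gene-count filtering and doublet flagging
## by co-expression of mutually exclusive lineage markers.

#' Per-cell QC metrics
#'
#' @param counts genes x cells count matrix (sparse or dense) with dimnames.
#' @return data.frame (class `cell_qc`) with one row per cell: `cell_id`,
#'   `total_umi`, `n_genes_detected` (genes with >= 1 UMI), `doublet_flag`,
#'   `doublet_reason`.
#' @export
compute_cell_qc <- function(counts) {
  if (is.null(dim(counts)) || nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("counts must be a non-empty genes x cells matrix")
  }
  qc <- data.frame(
    cell_id = colnames(counts),
    total_umi = as.integer(round(Matrix::colSums(counts))),
    n_genes_detected = as.integer(Matrix::colSums(counts > 0)),
    doublet_flag = FALSE,
    doublet_reason = "",
    stringsAsFactors = FALSE)
  class(qc) <- c("cell_qc", "data.frame")
  qc
}

#' QC thresholds on UMI and gene counts
#'
#' Upper bounds default to unbounded. Values are configuration, not
#' constants: per-dataset cutoffs belong to the data, the defaults are
#' tuned to separate the simulator's low-depth debris mode.
#'
#' @param min_umi,max_umi,min_genes,max_genes inclusive bounds.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umi = 500, max_umi = Inf,
                          min_genes = 200, max_genes = Inf) {
  if (min_umi > max_umi || min_genes > max_genes) {
    stop("lower thresholds must not exceed upper thresholds")
  }
  structure(list(min_umi = min_umi, max_umi = max_umi,
                 min_genes = min_genes, max_genes = max_genes),
            class = "qc_thresholds")
}

#' Filter cells on QC metrics and doublet flags
#'
#' Retains exactly the cells within all bounds and not flagged as doublets;
#' gene set and cell order are preserved. Filtering is idempotent.
#'
#' @param counts genes x cells matrix.
#' @param qc matching [compute_cell_qc()] table (after any doublet flagging).
#' @param thresholds a [qc_thresholds()].
#' @return The filtered matrix.
#' @export
filter_cells <- function(counts, qc, thresholds = qc_thresholds()) {
  stopifnot(inherits(qc, "data.frame"))
  if (!identical(qc$cell_id, colnames(counts))) {
    stop("qc table does not match the matrix cells")
  }
  keep <- qc$total_umi >= thresholds$min_umi &
    qc$total_umi <= thresholds$max_umi &
    qc$n_genes_detected >= thresholds$min_genes &
    qc$n_genes_detected <= thresholds$max_genes &
    !qc$doublet_flag
  if (!any(keep)) warning("no cells pass the QC thresholds")
  counts[, keep, drop = FALSE]
}

#' Define a mutually exclusive marker pair
#'
#' A cell co-expressing `gene_a` at >= `min_count_a` raw UMIs and `gene_b`
#' at >= `min_count_b` is flagged as a doublet: lineage-restricted markers
#' (e.g. the germline marker vasa versus the somatic marker traffic jam)
#' are not expressed together in a single cell. Thresholds act on raw
#' counts, which keeps the binary rule robust to normalisation.
#'
#' @param name label recorded as the flag reason.
#' @param gene_a,gene_b distinct gene identifiers.
#' @param min_count_a,min_count_b raw UMI thresholds (>= 1).
#' @return An `exclusive_pair` list.
#' @export
exclusive_pair <- function(name, gene_a, gene_b,
                           min_count_a = 5, min_count_b = 5) {
  if (identical(gene_a, gene_b)) stop("gene_a and gene_b must differ")
  if (min_count_a < 1 || min_count_b < 1) stop("count thresholds must be >= 1")
  structure(list(name = name, gene_a = gene_a, gene_b = gene_b,
                 min_count_a = min_count_a, min_count_b = min_count_b),
            class = "exclusive_pair")
}

#' Build exclusive pairs from two lineage marker sets
#'
#' Picks, from each set, the `n_pairs` markers that look most like clean
#' exclusive markers — bimodal across the dataset, i.e. a low median raw
#' count (most cells, the other lineage, do not express them) but a high
#' upper-quantile count (their own lineage expresses them strongly) — and
#' pairs them rank-for-rank. This is the in-silico analogue of choosing
#' strong, background-free lineage markers by eye.
#'
#' @param counts genes x cells matrix.
#' @param genes_a,genes_b marker gene sets of two mutually exclusive
#'   lineages.
#' @param n_pairs number of pairs.
#' @param min_count UMI threshold applied to both sides.
#' @return List of [exclusive_pair()] objects.
#' @export
build_exclusive_pairs <- function(counts, genes_a, genes_b,
                                  n_pairs = 5, min_count = 5) {
  .check_genes_present(c(genes_a, genes_b), rownames(counts), "marker")
  top <- function(g) {
    x <- .as_dense(counts[g, , drop = FALSE])
    ## background level: mean count among cells below the flagging
    ## threshold; a clean exclusive marker has near-zero background
    bg <- apply(x, 1, function(v) {
      lo <- v[v < min_count]
      if (!length(lo)) Inf else mean(lo)
    })
    q95 <- apply(x, 1, stats::quantile, probs = 0.95)
    clean <- bg <= 0.8
    if (sum(clean) >= n_pairs) {
      g <- g[clean]
      q95 <- q95[clean]
    }
    g[order(-q95, g)][seq_len(min(n_pairs, length(g)))]
  }
  ta <- top(genes_a)
  tb <- top(genes_b)
  n <- min(length(ta), length(tb))
  lapply(seq_len(n), function(i) {
    exclusive_pair(sprintf("pair%d", i), ta[i], tb[i], min_count, min_count)
  })
}

#' Flag doublets by mutually exclusive marker co-expression
#'
#' @param counts genes x cells raw count matrix.
#' @param qc a [compute_cell_qc()] table for the same cells.
#' @param pairs list of [exclusive_pair()] objects.
#' @return The qc table with `doublet_flag`/`doublet_reason` updated; the
#'   reason records the first matching pair. Flags accumulate (a cell
#'   already flagged stays flagged).
#' @export
flag_marker_doublets <- function(counts, qc, pairs) {
  if (inherits(pairs, "exclusive_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) >= 1L)
  if (!identical(qc$cell_id, colnames(counts))) {
    stop("qc table does not match the matrix cells")
  }
  for (p in pairs) {
    .check_genes_present(c(p$gene_a, p$gene_b), rownames(counts),
                         sprintf("exclusive pair '%s' gene", p$name))
  }
  for (p in pairs) {
    hit <- as.numeric(counts[p$gene_a, ]) >= p$min_count_a &
      as.numeric(counts[p$gene_b, ]) >= p$min_count_b
    newly <- hit & !qc$doublet_flag
    qc$doublet_flag[newly] <- TRUE
    qc$doublet_reason[newly] <- p$name
  }
  qc
}
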