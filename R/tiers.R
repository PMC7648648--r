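## Iterative tiered clustering: recursive community detection where each
## candidate split must pass a differential-expression quality gate (every
## subcluster needs >= Q gate genes) before it becomes a new tier.

#' Configuration for tiered clustering
#'
#' @param quality_genes Q, the minimum number of differential genes every
#'   subcluster must show for a split to be accepted (default 5).
#' @param de_alpha BH-adjusted p threshold for gate genes.
#' @param de_min_lfc minimum log2 fold change (expm1-scale means) for gate
#'   genes.
#' @param de_min_frac minimum fraction of subcluster cells expressing a
#'   gate gene.
#' @param resolutions strictly increasing community-detection resolutions
#'   tried per node; the lowest yielding >= 2 communities is used
#'   (coarse-to-fine).
#' @param knn_k neighbors for the shared-nearest-neighbor graph; reduced to
#'   `n - 1` with a warning on small nodes.
#' @param min_cells_to_split smallest node eligible for sub-clustering.
#' @param max_depth maximum tier depth.
#' @param local_embed recompute variable genes and PCA within each node
#'   (global components wash out fine subtypes).
#' @param n_local_hvg,n_local_pcs node-local embedding size.
#' @param snn_prune SNN edges with Jaccard weight below this are dropped.
#' @param direction count gate genes up-regulated in the subcluster only
#'   (`"up"`, default) or in either direction (`"both"`).
#' @param compare gate contrast: each subcluster versus the union of its
#'   siblings (`"siblings"`, default) or versus all other cells in the
#'   dataset (`"rest"`).
#' @param seed integer seed for community detection.
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(quality_genes = 5,
                              de_alpha = 0.05,
                              de_min_lfc = 1.0,
                              de_min_frac = 0.25,
                              resolutions = seq(0.1, 1.2, by = 0.1),
                              knn_k = 20,
                              min_cells_to_split = 50,
                              max_depth = 5,
                              local_embed = TRUE,
                              n_local_hvg = 1000,
                              n_local_pcs = 20,
                              snn_prune = 1 / 15,
                              direction = c("up", "both"),
                              compare = c("siblings", "rest"),
                              seed = 0L) {
  if (quality_genes < 1) stop("quality_genes must be >= 1")
  if (de_alpha <= 0 || de_alpha >= 1) stop("de_alpha must lie in (0, 1)")
  if (any(diff(resolutions) <= 0)) stop("resolutions must be strictly increasing")
  structure(list(quality_genes = as.integer(quality_genes),
                 de_alpha = de_alpha, de_min_lfc = de_min_lfc,
                 de_min_frac = de_min_frac, resolutions = resolutions,
                 knn_k = as.integer(knn_k),
                 min_cells_to_split = as.integer(min_cells_to_split),
                 max_depth = as.integer(max_depth),
                 local_embed = local_embed,
                 n_local_hvg = as.integer(n_local_hvg),
                 n_local_pcs = as.integer(n_local_pcs),
                 snn_prune = snn_prune,
                 direction = match.arg(direction),
                 compare = match.arg(compare),
                 seed = as.integer(seed)),
            class = "clustering_config")
}

## Shared-nearest-neighbor graph on embedding coordinates: k-NN by Euclidean
## distance, edges weighted by the Jaccard overlap of neighbor lists
## (self included, as is conventional), pruned below `prune`.
.snn_graph <- function(coords, k, prune = 1 / 15) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(coords))
  nn <- matrix(0L, n, k + 1L)
  for (i in seq_len(n)) {
    nn[i, ] <- order(d[i, ])[seq_len(k + 1L)]  # self sorts first (distance 0)
  }
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                              j = as.integer(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- methods::as(shared, "TsparseMatrix")
  i <- shared@i + 1L
  j <- shared@j + 1L
  w <- shared@x / (2 * (k + 1L) - shared@x)  # Jaccard
  keep <- i < j & w >= prune
  igraph::graph_from_data_frame(
    data.frame(from = i[keep], to = j[keep], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

## Node-local embedding: re-select variable genes and re-run PCA within the
## node, falling back to the provided global coordinates when the node is
## too small or local embedding is disabled.
.node_coords <- function(norm, emb, cells, config) {
  n <- length(cells)
  ## the root node is the full dataset: use the supplied (typically
  ## batch-corrected) global embedding rather than re-embedding
  if (!config$local_embed || n == ncol(norm) || n <= config$n_local_pcs + 1L) {
    return(emb$coords[cells, , drop = FALSE])
  }
  sub <- norm[, cells, drop = FALSE]
  nhvg <- min(config$n_local_hvg, nrow(sub))
  genes <- select_variable_genes(sub, nhvg)
  npc <- min(config$n_local_pcs, n - 1L, nhvg)
  embed_pca(sub, genes, n_components = npc)$coords
}

#' Cluster the cells of one node
#'
#' Builds a shared-nearest-neighbor graph on a node-local embedding and
#' runs modularity-based (Louvain) community detection, sweeping the
#' resolution grid from coarse to fine and keeping the lowest resolution
#' that yields at least two communities.
#'
#' @param norm normalized genes x cells matrix.
#' @param emb global [embed_pca()] embedding (fallback coordinates).
#' @param cells integer or character index of the node's cells.
#' @param config a [clustering_config()].
#' @return List with `labels` (integer community per cell, `NULL` when
#'   unsplittable), `resolution` used, and `unsplittable` flag.
#' @export
cluster_node <- function(norm, emb, cells, config = clustering_config()) {
  if (is.character(cells)) cells <- match(cells, colnames(norm))
  n <- length(cells)
  if (n < 2L) return(list(labels = NULL, resolution = NA_real_, unsplittable = TRUE))
  coords <- .node_coords(norm, emb, cells, config)
  if (all(stats::dist(coords) < 1e-12)) {
    return(list(labels = NULL, resolution = NA_real_, unsplittable = TRUE))
  }
  k <- config$knn_k
  if (n < k + 1L) {
    warning(sprintf("node has %d cells < knn_k + 1; using k = %d", n, n - 1L))
    k <- n - 1L
  }
  g <- .snn_graph(coords, k, config$snn_prune)
  for (r in config$resolutions) {
    set.seed(config$seed)
    cl <- igraph::cluster_louvain(g, resolution = r)
    memb <- igraph::membership(cl)
    if (length(unique(memb)) >= 2L) {
      return(list(labels = as.integer(memb), resolution = r,
                  unsplittable = FALSE, coords = coords))
    }
  }
  list(labels = NULL, resolution = NA_real_, unsplittable = TRUE,
       coords = coords)
}

## Coarse-to-fine candidate groupings of detected communities: average-
## linkage agglomeration of community centroids, cut into 2, 3, ..., C
## groups. With well-separated subtypes the community graph is
## disconnected, so no modularity resolution can return a coarser
## partition than its components; trying agglomerated 2-way (then 3-way,
## ...) cuts first realises the "coarsest split the gate can ratify" rule.
.candidate_groupings <- function(labels, coords) {
  levs <- sort(unique(labels))
  C <- length(levs)
  if (C == 2L) return(list(labels))
  cent <- t(vapply(levs, function(lv) {
    colMeans(coords[labels == lv, , drop = FALSE])
  }, numeric(ncol(coords))))
  hc <- stats::hclust(stats::dist(cent), method = "average")
  lapply(2:C, function(k) {
    grp <- stats::cutree(hc, k = k)
    as.integer(grp[match(labels, levs)])
  })
}

#' Differential-expression quality gate for a candidate split
#'
#' For every subcluster, each gene expressed in at least `de_min_frac` of
#' the subcluster's cells is tested with a two-sided Wilcoxon rank-sum test
#' against the union of the sibling subclusters; p-values are
#' Benjamini-Hochberg adjusted with the full gene count of the node as the
#' family size. A gene passes when adjusted p < `de_alpha`, |log2FC| >=
#' `de_min_lfc` with the subcluster on the high side (unless
#' `direction = "both"`), and the expression-fraction condition holds. The
#' split passes the gate iff at least two subclusters were proposed and
#' every one of them has >= `quality_genes` passing genes; subclusters with
#' fewer than 3 cells auto-fail.
#'
#' @param norm normalized genes x cells matrix.
#' @param cells index of the node's cells.
#' @param labels candidate subcluster label per cell.
#' @param config a [clustering_config()].
#' @param resolution resolution recorded in the report (informational).
#' @return A `gate_report`: list with `pass`, `resolution`, and `clusters`
#'   (data.frame: label, n_cells, n_pass_genes, pass).
#' @export
quality_gate <- function(norm, cells, labels, config = clustering_config(),
                         resolution = NA_real_) {
  if (is.character(cells)) cells <- match(cells, colnames(norm))
  stopifnot(length(labels) == length(cells))
  levs <- sort(unique(labels))
  if (length(levs) < 2L) stop("quality_gate needs at least two subcluster labels")
  x <- .as_dense(norm[, cells, drop = FALSE])
  n_family <- nrow(norm)
  rows <- lapply(levs, function(lv) {
    grp <- labels == lv
    n_in <- sum(grp)
    if (n_in < 3L) {
      return(data.frame(label = lv, n_cells = n_in, n_pass_genes = 0L,
                        pass = FALSE))
    }
    xx <- if (config$compare == "siblings") x else .as_dense(norm)
    gg <- if (config$compare == "siblings") grp else {
      seq_len(ncol(norm)) %in% cells[grp]
    }
    frac_in <- rowMeans(xx[, gg, drop = FALSE] > 0)
    cand <- which(frac_in >= config$de_min_frac)
    if (!length(cand)) {
      return(data.frame(label = lv, n_cells = n_in, n_pass_genes = 0L,
                        pass = FALSE))
    }
    ts <- .rank_sum(xx[cand, , drop = FALSE], gg)
    padj <- stats::p.adjust(ts$p_value, method = "BH", n = n_family)
    mean_in <- rowMeans(expm1(xx[cand, gg, drop = FALSE]))
    mean_out <- rowMeans(expm1(xx[cand, !gg, drop = FALSE]))
    lfc <- .log2_fc(mean_in, mean_out)
    ok_dir <- if (config$direction == "up") lfc >= config$de_min_lfc else
      abs(lfc) >= config$de_min_lfc
    n_pass <- sum(padj < config$de_alpha & ok_dir)
    data.frame(label = lv, n_cells = n_in, n_pass_genes = n_pass,
               pass = n_pass >= config$quality_genes)
  })
  clusters <- do.call(rbind, rows)
  structure(list(pass = all(clusters$pass) && nrow(clusters) >= 2L,
                 resolution = resolution, clusters = clusters),
            class = "gate_report")
}

#' @method print gate_report
#' @export
print.gate_report <- function(x, ...) {
  cat(sprintf("Quality gate: %s (resolution %s)\n",
              if (x$pass) "PASS" else "FAIL",
              format(x$resolution)))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Fit a tier tree by iterative gated clustering
#'
#' The central fitting function. Clusters the full dataset into tier-1
#' groups, then recursively re-clusters each group on a node-local
#' embedding; a split only becomes a new tier when it passes the
#' differential-expression [quality_gate()] (every subcluster must show at
#' least `quality_genes` gate genes). Splitting is coarse-to-fine twice
#' over: community detection uses the lowest resolution producing at least
#' two communities, and when more than two are found, agglomerated
#' groupings of those communities are gated from the 2-way cut upward and
#' the coarsest ratified grouping wins — so distantly related populations
#' separate in early tiers and closely related ones in later tiers. Nodes
#' that are too small, too deep, unsplittable, or with no gate-ratified
#' grouping become terminal clusters. Tier labels are zero-based dotted paths ("0", "0.1", ...);
#' siblings are numbered by decreasing size with ties broken by the
#' smallest member cell id.
#'
#' @param norm normalized genes x cells matrix (QC-filtered).
#' @param emb global [embed_pca()] embedding of the same cells (typically
#'   batch-corrected).
#' @param config a [clustering_config()].
#' @return A `tier_tree`: `nodes` data.frame (label, parent, n_cells,
#'   depth, terminal, resolution, gate_pass, supervised), `cell_labels`
#'   (named terminal label per cell), `gates` (gate report per attempted
#'   split, keyed by the parent label), and `config`.
#' @export
run_tiered_clustering <- function(norm, emb, config = clustering_config()) {
  if (ncol(norm) == 0L) stop("empty input matrix")
  stopifnot(inherits(emb, "embedding"),
            identical(rownames(emb$coords), colnames(norm)))
  cell_ids <- colnames(norm)
  nodes <- list()
  gates <- list()
  cell_labels <- stats::setNames(rep(NA_character_, length(cell_ids)), cell_ids)

  add_node <- function(label, parent, n, depth, terminal, resolution, gate_pass) {
    nodes[[length(nodes) + 1L]] <<- data.frame(
      label = label, parent = parent, n_cells = n, depth = depth,
      terminal = terminal, resolution = resolution, gate_pass = gate_pass,
      supervised = FALSE, stringsAsFactors = FALSE)
  }

  recurse <- function(cells, label, depth) {
    n <- length(cells)
    is_root <- label == ""
    finish <- function(resolution = NA_real_, gate_pass = NA) {
      lab <- if (is_root) "0" else label
      add_node(lab, if (is_root) NA_character_ else .parent_label(lab),
               n, max(depth, 1L), TRUE, resolution, gate_pass)
      cell_labels[cells] <<- lab
    }
    if (n < config$min_cells_to_split || depth >= config$max_depth) {
      return(finish())
    }
    cl <- cluster_node(norm, emb, cells, config)
    if (cl$unsplittable) return(finish())
    ## coarse-to-fine: accept the coarsest grouping of the detected
    ## communities that the gate ratifies
    gate <- NULL
    accepted <- NULL
    for (cand in .candidate_groupings(cl$labels, cl$coords)) {
      g <- quality_gate(norm, cells, cand, config, cl$resolution)
      if (is.null(gate)) gate <- g
      if (g$pass) {
        gate <- g
        accepted <- cand
        break
      }
    }
    gates[[if (is_root) "(root)" else label]] <<- gate
    if (is.null(accepted)) return(finish(cl$resolution, FALSE))
    if (!is_root) {
      add_node(label, .parent_label(label), n, depth, FALSE, cl$resolution, TRUE)
    }
    ## order siblings by decreasing size, ties by smallest member cell id
    groups <- split(cells, accepted)
    first_id <- vapply(groups, function(g) min(cell_ids[g]), "")
    groups <- groups[order(-lengths(groups), first_id)]
    for (i in seq_along(groups)) {
      child <- if (is_root) as.character(i - 1L) else
        paste(label, i - 1L, sep = ".")
      recurse(groups[[i]], child, depth + 1L)
    }
  }

  recurse(seq_along(cell_ids), "", 0L)
  nodes <- do.call(rbind, nodes)
  structure(list(nodes = nodes, cell_labels = cell_labels, gates = gates,
                 config = config),
            class = "tier_tree")
}

.parent_label <- function(label) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  if (length(parts) <= 1L) NA_character_ else
    paste(parts[-length(parts)], collapse = ".")
}

#' Supervised split of a terminal cluster by marker expression
#'
#' Splits a terminal node into the cells with normalized expression of
#' `gene` at or above `min_value` and the remainder — the sanctioned route
#' for rare populations that community detection cannot resolve (too few
#' cells for the gate). Both children are marked `supervised`.
#'
#' @param tree a [run_tiered_clustering()] tier tree.
#' @param norm the normalized matrix the tree was fitted on.
#' @param node terminal node label to split.
#' @param gene marker gene id.
#' @param min_value normalized expression threshold.
#' @return The updated `tier_tree`; a no-op with a warning when either side
#'   would be empty.
#' @export
split_cluster_by_marker <- function(tree, norm, node, gene, min_value) {
  stopifnot(inherits(tree, "tier_tree"))
  row <- match(node, tree$nodes$label)
  if (is.na(row)) stop(sprintf("node '%s' does not exist", node))
  if (!tree$nodes$terminal[row]) stop(sprintf("node '%s' is not terminal", node))
  .check_genes_present(gene, rownames(norm), "marker")
  cells <- names(tree$cell_labels)[tree$cell_labels == node]
  expr <- as.numeric(norm[gene, cells])
  hi <- cells[expr >= min_value]
  lo <- setdiff(cells, hi)
  if (!length(hi) || !length(lo)) {
    warning("threshold puts every cell on one side; no split performed")
    return(tree)
  }
  sides <- list(hi, lo)
  first_id <- vapply(sides, min, "")
  sides <- sides[order(-lengths(sides), first_id)]
  tree$nodes$terminal[row] <- FALSE
  for (i in seq_along(sides)) {
    lab <- paste(node, i - 1L, sep = ".")
    tree$nodes <- rbind(tree$nodes, data.frame(
      label = lab, parent = node, n_cells = length(sides[[i]]),
      depth = tree$nodes$depth[row] + 1L, terminal = TRUE,
      resolution = NA_real_, gate_pass = NA, supervised = TRUE,
      stringsAsFactors = FALSE))
    tree$cell_labels[sides[[i]]] <- lab
  }
  tree
}

#' @method print tier_tree
#' @export
print.tier_tree <- function(x, ...) {
  term <- x$nodes[x$nodes$terminal, ]
  cat(sprintf("Tier tree: %d cells, %d terminal clusters, max depth %d\n",
              length(x$cell_labels), nrow(term), max(x$nodes$depth)))
  cat("  terminal clusters:",
      paste(sprintf("%s (n=%d)", term$label, term$n_cells), collapse = ", "),
      "\n")
  invisible(x)
}

#' @method summary tier_tree
#' @export
summary.tier_tree <- function(object, ...) {
  cat(sprintf("Tier tree over %d cells\n", length(object$cell_labels)))
  print(object$nodes, row.names = FALSE)
  if (length(object$gates)) {
    cat("\nGate decisions:\n")
    for (nm in names(object$gates)) {
      g <- object$gates[[nm]]
      cat(sprintf("  %s: %s (min gate genes %d, resolution %s)\n", nm,
                  if (g$pass) "split accepted" else "split rejected",
                  min(g$clusters$n_pass_genes), format(g$resolution)))
    }
  }
  invisible(object)
}

#' Per-cell tier table
#'
#' @param x a `tier_tree`.
#' @param ... unused.
#' @return data.frame with `cell_id`, one `tier<k>` column per depth (the
#'   length-k prefix of the terminal label) and `terminal_label`.
#' @export
as.data.frame.tier_tree <- function(x, ...) {
  labs <- x$cell_labels
  parts <- strsplit(labs, ".", fixed = TRUE)
  kmax <- max(lengths(parts))
  out <- data.frame(cell_id = names(labs), stringsAsFactors = FALSE)
  for (k in seq_len(kmax)) {
    out[[paste0("tier", k)]] <- vapply(parts, function(p) {
      if (length(p) >= k) paste(p[seq_len(k)], collapse = ".") else
        paste(p, collapse = ".")
    }, "")
  }
  out$terminal_label <- unname(labs)
  rownames(out) <- NULL
  out
}

#' Plot a tier tree
#'
#' Draws the cluster hierarchy as a rooted tree, terminal clusters labelled
#' with their size.
#'
#' @param x a `tier_tree`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.tier_tree <- function(x, ...) {
  nd <- x$nodes
  labels <- c("root", nd$label)
  parents <- ifelse(is.na(nd$parent), "root", nd$parent)
  g <- igraph::graph_from_data_frame(
    data.frame(from = parents, to = nd$label),
    vertices = data.frame(name = labels[!duplicated(labels)]))
  sizes <- stats::setNames(c(length(x$cell_labels), nd$n_cells),
                           labels[!duplicated(labels)])
  igraph::V(g)$label <- sprintf("%s\n(%d)", igraph::V(g)$name,
                                sizes[igraph::V(g)$name])
  plot(g, layout = igraph::layout_as_tree(g, root = "root"),
       vertex.shape = "none", ...)
  invisible(x)
}

#' Serialize a tier tree to JSON
#'
#' Writes the node table and per-split gate reports as a JSON string
#' (requires the jsonlite package).
#'
#' @param tree a `tier_tree`.
#' @return JSON character scalar.
#' @export
tier_tree_json <- function(tree) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("tier_tree_json() requires the jsonlite package")
  }
  jsonlite::toJSON(list(
    nodes = tree$nodes,
    gates = lapply(tree$gates, function(g) {
      list(pass = g$pass, resolution = g$resolution, clusters = g$clusters)
    })), auto_unbox = TRUE, digits = NA, na = "null")
}
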