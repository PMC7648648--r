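## Trajectory inference: minimum spanning tree over group centroids in
## embedding space, projection of cells onto the backbone, geodesic
## pseudotime from a marker-defined root, fixed-size binning, binned
## expression profiles and trajectory differential expression.

#' Trajectory configuration
#'
#' @param n_components embedding dimensions used for the backbone; the
#'   default `"auto"` keeps the components whose eigenvalue exceeds both
#'   the Marchenko-Pastur noise edge of the gene-standardized data and 10%
#'   of the leading eigenvalue, so pure-noise directions do not bend the
#'   backbone.
#' @param n_groups k-means groups used as backbone nodes when no (or only
#'   one) cluster label is available.
#' @param bin_size cells per pseudotime bin (default 10).
#' @param seed integer seed (k-means initialisation).
#' @return A `trajectory_config` list.
#' @export
trajectory_config <- function(n_components = "auto", n_groups = 10,
                              bin_size = 10, seed = 1L) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  structure(list(n_components = if (identical(n_components, "auto"))
                   "auto" else as.integer(n_components),
                 n_groups = as.integer(n_groups),
                 bin_size = as.integer(bin_size),
                 seed = as.integer(seed)),
            class = "trajectory_config")
}

#' Fit a trajectory backbone
#'
#' Computes one centroid per cluster (or per k-means cell group when fewer
#' than two clusters are given), connects the centroids by their Euclidean
#' minimum spanning tree, and projects every cell orthogonally onto its
#' nearest backbone edge. Pseudotime is assigned separately by
#' [assign_pseudotime()] once a root is chosen.
#'
#' @param emb an [embed_pca()] embedding.
#' @param labels optional per-cell cluster labels; with fewer than two
#'   distinct labels, k-means grouping with `config$n_groups` centers is
#'   used (requires >= 50 cells).
#' @param config a [trajectory_config()].
#' @return A `trajectory`: centroids, MST (igraph, edge weights =
#'   centroid distances), per-cell edge assignment and offset, cell ids.
#' @export
fit_trajectory <- function(emb, labels = NULL, config = trajectory_config()) {
  stopifnot(inherits(emb, "embedding"))
  k <- if (identical(config$n_components, "auto")) {
    .signal_dims(emb)
  } else {
    config$n_components
  }
  coords <- emb$coords[, seq_len(min(k, ncol(emb$coords))), drop = FALSE]
  n <- nrow(coords)
  if (is.null(labels) || length(unique(labels)) < 2L) {
    if (n < 50L) stop("need >= 2 cluster labels or >= 50 cells for k-means grouping")
    set.seed(config$seed)
    km <- stats::kmeans(coords, centers = min(config$n_groups, n - 1L),
                        nstart = 5, iter.max = 50)
    labels <- km$cluster
  }
  labels <- as.character(labels)
  levs <- sort(unique(labels))
  if (length(levs) < 2L) stop("fewer than two backbone centroids")
  cent <- matrix(0, length(levs), ncol(coords),
                 dimnames = list(levs, colnames(coords)))
  for (k in seq_along(levs)) {
    cent[k, ] <- colMeans(coords[labels == levs[k], , drop = FALSE])
  }

  d <- as.matrix(stats::dist(cent))
  ## deterministic tie-break for duplicate centroids: perturb nothing,
  ## igraph MST is deterministic for a fixed edge order (label order here)
  full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(full, algorithm = "prim")

  ## project each cell onto the nearest point of any MST edge
  el <- igraph::as_edgelist(mst)
  proj <- .project_cells(coords, cent, el)
  structure(list(centroids = cent, mst = mst, edges = el,
                 edge_id = proj$edge, offset = proj$offset,
                 proj_dist = proj$dist,
                 cell_ids = rownames(coords),
                 config = config, pseudotime = NULL, root = NULL),
            class = "trajectory")
}

## Number of embedding components above the noise floor: eigenvalue must
## exceed the Marchenko-Pastur upper edge sigma^2 (1 + sqrt(p/n))^2 of the
## gene-standardized data (sigma^2 ~ 1) and 10% of the leading eigenvalue.
.signal_dims <- function(emb) {
  ev <- emb$eig
  if (is.null(ev)) return(ncol(emb$coords))
  edge <- (1 + sqrt(length(emb$genes) / emb$n_cells))^2
  k <- sum(ev > pmax(edge, 0.1 * ev[1]))
  min(max(1L, k), ncol(emb$coords))
}

## Orthogonal projection of points onto segments; returns, per cell, the
## nearest edge index, the distance along that edge from its first node,
## and the residual distance.
.project_cells <- function(coords, cent, el) {
  n <- nrow(coords)
  ne <- nrow(el)
  best_d <- rep(Inf, n)
  best_e <- integer(n)
  best_o <- numeric(n)
  for (e in seq_len(ne)) {
    a <- cent[el[e, 1], ]
    b <- cent[el[e, 2], ]
    ab <- b - a
    len2 <- sum(ab^2)
    diff <- sweep(coords, 2, a)
    tt <- if (len2 == 0) rep(0, n) else pmin(1, pmax(0, drop(diff %*% ab) / len2))
    res <- diff - outer(tt, ab)
    dd <- sqrt(rowSums(res^2))
    upd <- dd < best_d
    best_d[upd] <- dd[upd]
    best_e[upd] <- e
    best_o[upd] <- tt[upd] * sqrt(len2)
  }
  list(edge = best_e, offset = best_o, dist = best_d)
}

#' @method print trajectory
#' @export
print.trajectory <- function(x, ...) {
  deg <- igraph::degree(x$mst)
  cat(sprintf("Trajectory backbone: %d centroids, %d edges (%s), %d cells\n",
              nrow(x$centroids), nrow(x$edges),
              if (max(deg) <= 2) "simple path" else "branched",
              length(x$cell_ids)))
  if (!is.null(x$pseudotime)) {
    cat(sprintf("  pseudotime assigned from root '%s'\n", x$root))
  }
  invisible(x)
}

#' Assign pseudotime from a root
#'
#' Pseudotime is the geodesic distance along the backbone from the root
#' endpoint to each cell's projected position, min-max scaled to [0, 1].
#' The root is either an explicit backbone node / cell id, or a
#' `(marker, extremum)` rule: among the backbone's endpoints (degree-1
#' nodes), the one whose cells have the minimal (or maximal) mean
#' normalized marker expression becomes the root — e.g. picking the
#' trajectory end with the lowest level of a differentiation gene as the
#' start.
#'
#' @param traj a [fit_trajectory()] trajectory.
#' @param root_marker,root_extremum marker-based root rule (`root_extremum`
#'   is "min" or "max"); requires `norm`.
#' @param root_cell alternatively, a cell id whose backbone node becomes
#'   the root.
#' @param norm normalized matrix (needed for the marker rule).
#' @return The trajectory with `pseudotime` (named, in [0, 1]) and `root`
#'   filled in.
#' @export
assign_pseudotime <- function(traj, root_marker = NULL,
                              root_extremum = c("min", "max"),
                              root_cell = NULL, norm = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  root_extremum <- match.arg(root_extremum)
  deg <- igraph::degree(traj$mst)
  endpoints <- names(deg)[deg == 1L]
  if (!is.null(root_cell)) {
    i <- match(root_cell, traj$cell_ids)
    if (is.na(i)) stop(sprintf("cell '%s' not in the trajectory", root_cell))
    e <- traj$edge_id[i]
    half <- traj$offset[i] <= .edge_lengths(traj)[e] / 2
    root <- traj$edges[e, if (half) 1 else 2]
  } else {
    if (is.null(root_marker) || is.null(norm)) {
      stop("provide either root_cell, or root_marker together with norm")
    }
    .check_genes_present(root_marker, rownames(norm), "root marker")
    expr <- as.numeric(norm[root_marker, traj$cell_ids])
    ## cells attached to edges incident to each endpoint define its level
    mean_at <- vapply(endpoints, function(v) {
      inc <- which(traj$edges[, 1] == v | traj$edges[, 2] == v)
      cells <- traj$edge_id %in% inc
      if (!any(cells)) return(NA_real_)
      mean(expr[cells])
    }, numeric(1))
    mean_at <- mean_at[!is.na(mean_at)]
    if (!length(mean_at)) stop("no cells project near any backbone endpoint")
    root <- names(mean_at)[if (root_extremum == "min") which.min(mean_at) else
      which.max(mean_at)]
  }
  dists <- igraph::distances(traj$mst, v = root)[1, ]
  lens <- .edge_lengths(traj)
  a <- traj$edges[traj$edge_id, 1]
  b <- traj$edges[traj$edge_id, 2]
  pt <- pmin(dists[a] + traj$offset,
             dists[b] + lens[traj$edge_id] - traj$offset)
  rng <- range(pt)
  pt <- if (diff(rng) == 0) rep(0, length(pt)) else (pt - rng[1]) / diff(rng)
  traj$pseudotime <- stats::setNames(pt, traj$cell_ids)
  traj$root <- root
  traj
}

.edge_lengths <- function(traj) {
  vapply(seq_len(nrow(traj$edges)), function(e) {
    sqrt(sum((traj$centroids[traj$edges[e, 1], ] -
                traj$centroids[traj$edges[e, 2], ])^2))
  }, numeric(1))
}

#' Bin cells by pseudotime
#'
#' Sorts cells by pseudotime (stable tie-break on the cell id) and chunks
#' them into consecutive bins of `bin_size`; the final bin may be smaller,
#' or is merged into its predecessor when `merge_last` is set. Bin sizes
#' always sum to the number of cells.
#'
#' @param pseudotime named numeric vector (names = cell ids).
#' @param bin_size cells per bin (>= 1).
#' @param merge_last merge a trailing partial bin into the previous bin.
#' @return Named integer vector of 1-based bin indices, in the input
#'   cell order.
#' @export
bin_by_pseudotime <- function(pseudotime, bin_size = 10, merge_last = FALSE) {
  if (!length(pseudotime)) stop("empty pseudotime vector")
  if (bin_size < 1) stop("bin_size must be >= 1")
  ids <- names(pseudotime)
  if (is.null(ids)) ids <- as.character(seq_along(pseudotime))
  ord <- order(pseudotime, ids)
  n <- length(pseudotime)
  bins_sorted <- ceiling(seq_len(n) / bin_size)
  if (merge_last && n %% bin_size != 0 && max(bins_sorted) > 1L) {
    bins_sorted[bins_sorted == max(bins_sorted)] <- max(bins_sorted) - 1L
  }
  bins <- integer(n)
  bins[ord] <- bins_sorted
  stats::setNames(bins, ids)
}

#' Binned pseudotime expression profile
#'
#' Mean normalized expression per pseudotime bin, optionally smoothed with
#' a centered moving average over `smoothing_window` bins, then (when
#' `scale` is set, for display export) min-max scaled per gene to [0, 1];
#' constant genes map to all-zero.
#'
#' @param norm normalized genes x cells matrix.
#' @param bins [bin_by_pseudotime()] assignments for the same cells.
#' @param genes genes to profile.
#' @param smoothing_window moving-average width in bins (1 = none; must
#'   not exceed the number of bins).
#' @param scale min-max scale each gene's profile.
#' @return bins x genes numeric matrix.
#' @export
pseudotime_profile <- function(norm, bins, genes, smoothing_window = 1,
                               scale = TRUE) {
  .check_genes_present(genes, rownames(norm))
  stopifnot(length(bins) == ncol(norm))
  nb <- max(bins)
  if (smoothing_window > nb) stop("smoothing window exceeds the bin count")
  ub <- sort(unique(bins))
  prof <- matrix(0, length(ub), length(genes),
                 dimnames = list(ub, genes))
  for (k in seq_along(ub)) {
    prof[k, ] <- Matrix::rowMeans(norm[genes, bins == ub[k], drop = FALSE])
  }
  dn <- dimnames(prof)
  if (smoothing_window > 1) {
    w <- smoothing_window
    sm <- apply(prof, 2, function(v) {
      vapply(seq_along(v), function(i) {
        lo <- max(1, i - (w - 1) %/% 2)
        hi <- min(length(v), i + w %/% 2)
        mean(v[lo:hi])
      }, numeric(1))
    })
    prof <- matrix(sm, nrow = nrow(prof), dimnames = dn)
  }
  if (scale) {
    sc <- apply(prof, 2, function(v) {
      r <- range(v)
      if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
    })
    prof <- matrix(sc, nrow = nrow(prof), dimnames = dn)
  }
  prof
}

#' Pseudotime-dependent differential expression
#'
#' Spearman correlation of every gene with pseudotime, BH-adjusted;
#' a gene is called significant when adjusted p < `alpha`. Constant genes
#' get rho = 0 and p = 1 by convention.
#'
#' @param norm normalized genes x cells matrix (>= 20 cells).
#' @param pseudotime per-cell pseudotime (non-constant).
#' @param alpha significance threshold on adjusted p.
#' @return data.frame: gene, rho, p_value, p_adjusted, significant.
#' @export
trajectory_de <- function(norm, pseudotime, alpha = 0.05) {
  stopifnot(length(pseudotime) == ncol(norm))
  if (ncol(norm) < 20L) stop("trajectory DE needs >= 20 cells")
  if (stats::sd(pseudotime) == 0) stop("pseudotime is constant")
  sp <- .spearman_rows(.as_dense(norm), pseudotime)
  out <- data.frame(gene = rownames(norm), rho = sp$rho,
                    p_value = sp$p_value,
                    p_adjusted = stats::p.adjust(sp$p_value, method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Intersect trajectory DE results with a gene list
#'
#' Restricts the significant genes to those in `gene_list` (case-sensitive
#' exact id matching), preserving all statistics — e.g. intersecting
#' pseudotime-regulated genes with a transcription-factor annotation.
#'
#' @param de a [trajectory_de()] result.
#' @param gene_list character vector of gene ids.
#' @return The filtered data.frame (possibly empty).
#' @export
intersect_with_gene_list <- function(de, gene_list) {
  de[de$significant & de$gene %in% gene_list, , drop = FALSE]
}
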