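## Synthetic scRNA-seq count generator: hierarchical cell types with planted
## marker genes, replicate batches, doublets and continuous gradients, all
## with recorded ground truth so every downstream stage is testable.

#' Specify a hierarchical cell-type simulation
#'
#' Describes a tree of cell types, each non-root node carrying a disjoint
#' set of planted marker genes that are up-regulated (multiplicatively) in
#' every cell descending from that node. Counts are negative-binomial with
#' log-normal per-gene baseline means, log-normal library sizes, and a
#' per-gene per-batch multiplicative log-normal batch effect.
#'
#' @param nodes data.frame with columns `name`, `parent` (`NA` for the root)
#'   and `n_cells` (total cells for a leaf, split as evenly as possible
#'   across batches; internal nodes use 0). An optional `fold` column
#'   overrides `marker_fold_change` per node.
#' @param markers_per_node number of marker genes planted per non-root node.
#' @param marker_fold_change multiplicative up-regulation (>= 1) of a node's
#'   markers in that node's cells.
#' @param baseline_mean_log_mu,baseline_mean_log_sigma log-normal parameters
#'   of the per-gene baseline relative expression.
#' @param dispersion negative-binomial dispersion (inverse `size`); variance
#'   is `mu + dispersion * mu^2`.
#' @param n_genes total genes.
#' @param n_batches replicate batches.
#' @param batch_sigma SD of the per-gene per-batch multiplicative log-noise.
#' @param library_size_log_mu,library_size_log_sigma log-normal library-size
#'   parameters.
#' @param seed integer seed; identical specs give bit-identical output.
#' @return An object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(nodes,
                           markers_per_node = 50,
                           marker_fold_change = 8,
                           baseline_mean_log_mu = 0,
                           baseline_mean_log_sigma = 1.2,
                           dispersion = 0.1,
                           n_genes = 2000,
                           n_batches = 3,
                           batch_sigma = 0.1,
                           library_size_log_mu = log(3000),
                           library_size_log_sigma = 0.25,
                           seed = 1L) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "parent", "n_cells") %in% names(nodes)))
  if (anyDuplicated(nodes$name)) stop("node names must be unique")
  roots <- nodes$name[is.na(nodes$parent)]
  if (length(roots) != 1L) stop("the node tree must have exactly one root")
  bad <- setdiff(nodes$parent[!is.na(nodes$parent)], nodes$name)
  if (length(bad)) stop("unknown parent node(s): ", paste(bad, collapse = ", "))
  if (!"fold" %in% names(nodes)) nodes$fold <- marker_fold_change
  nodes$fold[is.na(nodes$fold)] <- marker_fold_change
  if (any(nodes$fold < 1)) stop("marker fold changes must be >= 1")
  if (marker_fold_change < 1) stop("marker_fold_change must be >= 1")
  n_marked <- sum(!is.na(nodes$parent)) * markers_per_node
  if (n_marked > n_genes) {
    stop(sprintf("n_genes (%d) is smaller than the %d marker genes required",
                 n_genes, n_marked))
  }
  if (dispersion <= 0 || batch_sigma < 0 || n_batches < 1) {
    stop("dispersion must be > 0, batch_sigma >= 0, n_batches >= 1")
  }
  structure(list(nodes = nodes, root = roots,
                 markers_per_node = as.integer(markers_per_node),
                 marker_fold_change = marker_fold_change,
                 baseline_mean_log_mu = baseline_mean_log_mu,
                 baseline_mean_log_sigma = baseline_mean_log_sigma,
                 dispersion = dispersion, n_genes = as.integer(n_genes),
                 n_batches = as.integer(n_batches), batch_sigma = batch_sigma,
                 library_size_log_mu = library_size_log_mu,
                 library_size_log_sigma = library_size_log_sigma,
                 seed = as.integer(seed)),
            class = "hierarchy_spec")
}

#' Two-lineage nested example hierarchy
#'
#' The standard simulated scene used throughout the test suite: a germline
#' leaf and a somatic branch that splits into two subtypes (emulating, e.g.,
#' germ cells versus two related follicle-cell populations). Tier-1 lineage
#' markers can be given a stronger fold change than the subtype markers,
#' reflecting that cross-lineage markers such as vasa and traffic jam are
#' near-mutually-exclusive while within-lineage subtype markers are merely
#' enriched.
#'
#' @param cells_per_leaf cells per terminal type.
#' @param fold fold change of subtype (tier-2) markers.
#' @param lineage_fold fold change of the two tier-1 lineage marker sets.
#' @param seed integer seed.
#' @param ... passed to [hierarchy_spec()].
#' @return A `hierarchy_spec`.
#' @export
example_hierarchy_spec <- function(cells_per_leaf = 300, fold = 8,
                                   lineage_fold = fold, seed = 1L, ...) {
  nodes <- data.frame(
    name = c("root", "germ", "soma", "somaA", "somaB"),
    parent = c(NA, "root", "root", "soma", "soma"),
    n_cells = c(0, cells_per_leaf, 0, cells_per_leaf, cells_per_leaf),
    fold = c(NA, lineage_fold, lineage_fold, fold, fold))
  hierarchy_spec(nodes, marker_fold_change = fold, seed = seed, ...)
}

.leaf_nodes <- function(nodes) {
  setdiff(nodes$name, nodes$parent[!is.na(nodes$parent)])
}

.node_path <- function(nodes, name) {
  path <- character()
  cur <- name
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- nodes$parent[match(cur, nodes$name)]
  }
  path
}

#' Simulate counts from a hierarchical cell-type specification
#'
#' Draws a sparse genes x cells UMI count matrix. Every cell of a leaf type
#' has the markers of the leaf and of all its ancestors up-regulated by the
#' node-specific fold before per-cell renormalisation to a log-normal
#' library size; counts are negative-binomial.
#'
#' @param spec a [hierarchy_spec()].
#' @return A `sim_scene`: list with `counts` (dgCMatrix, genes x cells),
#'   `truth` (data.frame: cell_id, batch, tier_path, is_doublet, parent_a,
#'   parent_b, t), `markers` (named list: node -> planted marker gene ids)
#'   and `spec`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  set.seed(spec$seed)
  nodes <- spec$nodes
  genes <- sprintf("G%06d", seq_len(spec$n_genes))

  weights <- stats::rlnorm(spec$n_genes, spec$baseline_mean_log_mu,
                           spec$baseline_mean_log_sigma)
  marked_nodes <- nodes$name[!is.na(nodes$parent)]
  marker_pool <- sample.int(spec$n_genes, length(marked_nodes) * spec$markers_per_node)
  markers <- split(marker_pool,
                   rep(seq_along(marked_nodes), each = spec$markers_per_node))
  names(markers) <- marked_nodes

  batch_fac <- matrix(exp(stats::rnorm(spec$n_genes * spec$n_batches, 0,
                                       spec$batch_sigma)),
                      nrow = spec$n_genes, ncol = spec$n_batches)

  leaves <- .leaf_nodes(nodes)
  leaves <- leaves[nodes$n_cells[match(leaves, nodes$name)] > 0]
  if (!length(leaves)) stop("no leaf has n_cells > 0")

  ## expected relative expression per leaf type
  type_mu <- lapply(leaves, function(lf) {
    m <- weights
    for (nd in .node_path(nodes, lf)) {
      if (nd %in% names(markers)) {
        m[markers[[nd]]] <- m[markers[[nd]]] * nodes$fold[match(nd, nodes$name)]
      }
    }
    m
  })
  names(type_mu) <- leaves

  cols <- list()
  meta <- list()
  batch_counter <- integer(spec$n_batches)
  for (lf in leaves) {
    n <- nodes$n_cells[match(lf, nodes$name)]
    per_batch <- diff(round(seq(0, n, length.out = spec$n_batches + 1)))
    path <- paste(setdiff(.node_path(nodes, lf), spec$root), collapse = "/")
    for (b in seq_len(spec$n_batches)) {
      nb <- per_batch[b]
      if (nb == 0) next
      mu_b <- type_mu[[lf]] * batch_fac[, b]
      p <- mu_b / sum(mu_b)
      L <- stats::rlnorm(nb, spec$library_size_log_mu, spec$library_size_log_sigma)
      cnt <- matrix(stats::rnbinom(spec$n_genes * nb,
                                   mu = outer(p, L),
                                   size = 1 / spec$dispersion),
                    nrow = spec$n_genes)
      idx <- batch_counter[b] + seq_len(nb)
      batch_counter[b] <- batch_counter[b] + nb
      ids <- sprintf("CELL-%d-%05d", b, idx)
      cols[[length(cols) + 1L]] <- cnt
      meta[[length(meta) + 1L]] <- data.frame(
        cell_id = ids, batch = b, tier_path = path,
        is_doublet = FALSE, parent_a = NA_character_,
        parent_b = NA_character_, t = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  truth <- do.call(rbind, meta)
  rownames(counts) <- genes
  colnames(counts) <- truth$cell_id
  ord <- order(truth$cell_id)
  counts <- counts[, ord, drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                 truth = truth,
                 markers = lapply(markers, function(i) genes[i]),
                 spec = spec),
            class = "sim_scene")
}

#' Binomially downsample a count vector or matrix to a target library size
#'
#' Each count is thinned `Binomial(count, target / total)` column-wise; used
#' for doublet library matching and for constructing low-depth "debris"
#' cells in tests.
#'
#' @param counts genes x cells matrix (sparse or dense) or a single column.
#' @param target target library size per column (recycled).
#' @return Matrix of the same shape with thinned integer counts.
#' @export
downsample_counts <- function(counts, target) {
  one <- is.null(dim(counts))
  m <- if (one) matrix(counts, ncol = 1) else .as_dense(counts)
  target <- rep_len(target, ncol(m))
  for (j in seq_len(ncol(m))) {
    tot <- sum(m[, j])
    p <- min(1, target[j] / tot)
    if (p < 1) m[, j] <- stats::rbinom(nrow(m), m[, j], p)
  }
  if (one) m[, 1] else m
}

#' Append cross-lineage doublets to a simulated scene
#'
#' Each doublet is the gene-wise sum of two parent cells sampled uniformly
#' from distinct tier-1 branches, then binomially downsampled to a library
#' size drawn from the singlet library-size distribution (so doublets are
#' not separable by depth alone). Truth labels are extended.
#'
#' @param scene a `sim_scene` from [simulate_counts()].
#' @param rate doublet fraction in `[0, 1)`; `round(rate * n_cells)` doublets
#'   are appended.
#' @param seed integer seed.
#' @return The updated `sim_scene`.
#' @export
inject_doublets <- function(scene, rate, seed = 1L) {
  stopifnot(inherits(scene, "sim_scene"))
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)")
  }
  singlet <- !scene$truth$is_doublet
  tier1 <- vapply(strsplit(scene$truth$tier_path, "/"), `[`, "", 1)
  if (length(unique(tier1[singlet])) < 2L) {
    stop("doublet injection requires at least two tier-1 branches")
  }
  n_dbl <- round(rate * sum(singlet))
  if (n_dbl == 0) return(scene)
  set.seed(seed)
  totals <- Matrix::colSums(scene$counts)[singlet]
  idx_all <- which(singlet)
  pa <- sample(idx_all, n_dbl, replace = TRUE)
  pb <- vapply(pa, function(i) {
    pool <- idx_all[tier1[idx_all] != tier1[i]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
  L <- sample(totals, n_dbl, replace = TRUE)
  dbl <- .as_dense(scene$counts[, pa, drop = FALSE]) +
    .as_dense(scene$counts[, pb, drop = FALSE])
  dbl <- downsample_counts(dbl, L)
  ids <- sprintf("CELL-DBL-%05d", seq_len(n_dbl))
  colnames(dbl) <- ids
  rownames(dbl) <- rownames(scene$counts)
  scene$counts <- cbind(scene$counts, Matrix::Matrix(dbl, sparse = TRUE))
  scene$truth <- rbind(scene$truth, data.frame(
    cell_id = ids, batch = scene$truth$batch[pa],
    tier_path = NA_character_, is_doublet = TRUE,
    parent_a = scene$truth$cell_id[pa], parent_b = scene$truth$cell_id[pb],
    t = NA_real_, stringsAsFactors = FALSE))
  scene
}

#' Specify a continuous-gradient simulation
#'
#' Cells are positioned uniformly on a latent differentiation coordinate
#' t in [0, 1]; each monotone gene responds to t with a linear or sigmoid
#' log-scale trend of the given direction and amplitude, on top of the same
#' negative-binomial noise model as [hierarchy_spec()].
#'
#' @param n_cells,n_genes scene dimensions.
#' @param monotone_genes data.frame with columns `gene` (index or id),
#'   `direction` ("up"/"down"), `amplitude` (> 0, log-scale range) and
#'   optionally `shape` ("sigmoid" or "linear"). If `NULL`, a default panel
#'   of `n_up` + `n_down` sigmoid genes of amplitude `amplitude` is planted.
#' @param n_up,n_down,amplitude,shape defaults for the planted panel.
#' @param baseline_mean_log_mu,baseline_mean_log_sigma,dispersion
#'   noise model as in [hierarchy_spec()].
#' @param library_size_log_mu,library_size_log_sigma library-size model.
#' @param seed integer seed.
#' @return An object of class `gradient_spec`.
#' @export
gradient_spec <- function(n_cells = 500, n_genes = 1000,
                          monotone_genes = NULL,
                          n_up = 60, n_down = 60, amplitude = 2,
                          shape = "sigmoid",
                          baseline_mean_log_mu = 0,
                          baseline_mean_log_sigma = 1.2,
                          dispersion = 0.1,
                          library_size_log_mu = log(3000),
                          library_size_log_sigma = 0.25,
                          seed = 1L) {
  if (is.null(monotone_genes)) {
    if (n_up + n_down < 1) stop("at least one monotone gene is required")
    monotone_genes <- data.frame(
      gene = seq_len(n_up + n_down),
      direction = rep(c("up", "down"), c(n_up, n_down)),
      amplitude = amplitude, shape = shape, stringsAsFactors = FALSE)
  }
  monotone_genes <- as.data.frame(monotone_genes, stringsAsFactors = FALSE)
  if (!nrow(monotone_genes)) stop("monotone_genes must be non-empty")
  if (!"shape" %in% names(monotone_genes)) monotone_genes$shape <- shape
  if (!all(monotone_genes$direction %in% c("up", "down"))) {
    stop("directions must be 'up' or 'down'")
  }
  if (any(monotone_genes$amplitude <= 0)) stop("amplitudes must be > 0")
  if (!all(monotone_genes$shape %in% c("sigmoid", "linear"))) {
    stop("shapes must be 'sigmoid' or 'linear'")
  }
  if (is.numeric(monotone_genes$gene) &&
      any(monotone_genes$gene < 1 | monotone_genes$gene > n_genes)) {
    stop("monotone gene index out of range for n_genes = ", n_genes)
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 monotone_genes = monotone_genes,
                 baseline_mean_log_mu = baseline_mean_log_mu,
                 baseline_mean_log_sigma = baseline_mean_log_sigma,
                 dispersion = dispersion,
                 library_size_log_mu = library_size_log_mu,
                 library_size_log_sigma = library_size_log_sigma,
                 seed = as.integer(seed)),
            class = "gradient_spec")
}

#' Simulate a continuous differentiation gradient
#'
#' @param spec a [gradient_spec()].
#' @return A `sim_scene` whose truth records the latent position `t`
#'   (`tier_path` is `"gradient"`, batch 1).
#' @export
simulate_gradient <- function(spec) {
  stopifnot(inherits(spec, "gradient_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%06d", seq_len(spec$n_genes))
  weights <- stats::rlnorm(spec$n_genes, spec$baseline_mean_log_mu,
                           spec$baseline_mean_log_sigma)
  tt <- stats::runif(spec$n_cells)
  mg <- spec$monotone_genes
  gi <- if (is.numeric(mg$gene)) as.integer(mg$gene) else match(mg$gene, genes)
  if (anyNA(gi) || any(gi < 1 | gi > spec$n_genes)) stop("monotone gene out of range")

  ## log-scale trend, centred at t = 0.5 so amplitude is the full range
  trend <- function(shape, t) {
    if (shape == "linear") t - 0.5 else 1 / (1 + exp(-10 * (t - 0.5))) - 0.5
  }
  log_mu <- matrix(log(weights), nrow = spec$n_genes, ncol = spec$n_cells)
  for (k in seq_len(nrow(mg))) {
    s <- if (mg$direction[k] == "up") 1 else -1
    log_mu[gi[k], ] <- log_mu[gi[k], ] +
      s * mg$amplitude[k] * trend(mg$shape[k], tt)
  }
  mu <- exp(log_mu)
  mu <- sweep(mu, 2, colSums(mu), "/")
  L <- stats::rlnorm(spec$n_cells, spec$library_size_log_mu,
                     spec$library_size_log_sigma)
  mu <- sweep(mu, 2, L, "*")
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
                nrow = spec$n_genes)
  ids <- sprintf("CELL-1-%05d", seq_len(spec$n_cells))
  rownames(cnt) <- genes
  colnames(cnt) <- ids
  truth <- data.frame(cell_id = ids, batch = 1L, tier_path = "gradient",
                      is_doublet = FALSE, parent_a = NA_character_,
                      parent_b = NA_character_, t = tt,
                      stringsAsFactors = FALSE)
  structure(list(counts = Matrix::Matrix(cnt, sparse = TRUE), truth = truth,
                 markers = list(gradient = genes[unique(gi)]), spec = spec),
            class = "sim_scene")
}

#' Combine two simulated scenes over a shared gene space
#'
#' Appends the cells of `b` to `a`; both scenes must have identical gene
#' identifiers. Useful to embed a continuum (e.g. a differentiating lineage)
#' next to discrete types.
#'
#' @param a,b `sim_scene` objects with identical rownames.
#' @return A combined `sim_scene`.
#' @export
combine_scenes <- function(a, b) {
  stopifnot(inherits(a, "sim_scene"), inherits(b, "sim_scene"))
  if (!identical(rownames(a$counts), rownames(b$counts))) {
    stop("scenes must share an identical gene space")
  }
  bt <- b$truth
  bc <- b$counts
  clash <- bt$cell_id %in% a$truth$cell_id
  if (any(clash)) {
    bt$cell_id[clash] <- paste0(bt$cell_id[clash], "-2")
    colnames(bc)[clash] <- bt$cell_id[clash]
  }
  structure(list(counts = cbind(a$counts, bc),
                 truth = rbind(a$truth, bt),
                 markers = c(a$markers, b$markers),
                 spec = list(a$spec, b$spec)),
            class = "sim_scene")
}

#' @method print sim_scene
#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf("Simulated scene: %d genes x %d cells (%d doublets)\n",
              nrow(x$counts), ncol(x$counts), sum(x$truth$is_doublet)))
  tp <- table(x$truth$tier_path, useNA = "ifany")
  cat("  cell types:", paste(sprintf("%s=%d", names(tp), tp), collapse = ", "),
      "\n")
  invisible(x)
}
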