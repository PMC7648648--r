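# Construct a normalized matrix with two cell groups and a chosen number of
# clean gate genes per side; remaining genes are exchangeable noise.
gated_toy <- function(n_pass_a, n_pass_b, n_per_side = 30, n_genes = 120,
                      seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_side
  m <- matrix(stats::rpois(n_genes * n, 3), n_genes, n)
  a <- seq_len(n_per_side)
  for (g in seq_len(n_pass_a)) m[g, a] <- m[g, a] + 40
  for (g in seq_len(n_pass_b)) m[n_pass_a + g, -a] <- m[n_pass_a + g, -a] + 40
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("c%03d", seq_len(n)))
  list(norm = Matrix::Matrix(log1p(m), sparse = TRUE),
       labels = rep(1:2, each = n_per_side))
}

test_that("quality gate enforces the >= Q distinct-gene rule per subcluster", {
  toy <- gated_toy(7, 7)
  gate <- quality_gate(toy$norm, seq_len(ncol(toy$norm)), toy$labels,
                       clustering_config(quality_genes = 5))
  expect_true(gate$pass)
  expect_true(all(gate$clusters$n_pass_genes >= 7))

  # a side with only 3 distinct genes fails the >= 5 quality measure
  weak <- gated_toy(7, 3)
  gate2 <- quality_gate(weak$norm, seq_len(ncol(weak$norm)), weak$labels,
                        clustering_config(quality_genes = 5))
  expect_false(gate2$pass)
  expect_equal(gate2$clusters$n_pass_genes[2], 3)

  # tiny subclusters auto-fail
  tiny <- gated_toy(7, 7)
  lab <- tiny$labels
  lab[lab == 2] <- 1
  lab[1:2] <- 2
  gate3 <- quality_gate(tiny$norm, seq_len(ncol(tiny$norm)), lab,
                        clustering_config())
  expect_false(gate3$clusters$pass[gate3$clusters$label == 2])
})

test_that("random splits of homogeneous data rarely pass the gate", {
  passes <- vapply(1:20, function(s) {
    scene <- homogeneous_scene(300, 800, seed = s)
    norm <- normalize_log_cp10k(scene$counts)
    set.seed(s + 1000)
    labels <- sample(rep(1:2, length.out = ncol(norm)))
    quality_gate(norm, seq_len(ncol(norm)), labels, clustering_config())$pass
  }, logical(1))
  expect_lte(mean(passes), 0.05)
})

test_that("gate pass rate on the true split is monotone in marker fold change", {
  npass <- vapply(c(1, 2, 4, 8), function(fold) {
    nodes <- data.frame(name = c("root", "a", "b"),
                        parent = c(NA, "root", "root"),
                        n_cells = c(0, 100, 100))
    spec <- hierarchy_spec(nodes, markers_per_node = 20,
                           marker_fold_change = fold, n_genes = 500,
                           n_batches = 1, batch_sigma = 0, seed = 77)
    scene <- simulate_counts(spec)
    norm <- normalize_log_cp10k(scene$counts)
    gate <- quality_gate(norm, seq_len(ncol(norm)),
                         as.integer(factor(scene$truth$tier_path)),
                         clustering_config())
    min(gate$clusters$n_pass_genes)
  }, numeric(1))
  expect_false(is.unsorted(npass))
  expect_equal(npass[1], 0)
  expect_gte(npass[4], 5)
})

test_that("cluster_node separates blobs and degrades gracefully", {
  set.seed(13)
  coords <- rbind(matrix(rnorm(60 * 2), 60, 2),
                  matrix(rnorm(60 * 2, mean = 12), 60, 2))
  rownames(coords) <- sprintf("c%03d", 1:120)
  norm <- Matrix::Matrix(matrix(1, 5, 120,
                                dimnames = list(letters[1:5],
                                                rownames(coords))),
                         sparse = TRUE)
  cfg <- clustering_config(local_embed = FALSE, seed = 1)
  cl <- cluster_node(norm, fake_embedding(coords), seq_len(120), cfg)
  expect_false(cl$unsplittable)
  truth <- rep(1:2, each = 60)
  expect_gte(ari(cl$labels, truth), 0.9)

  # small node: k reduced with a warning
  expect_warning(
    cluster_node(norm, fake_embedding(coords[1:15, ]), 1:15, cfg),
    "knn_k")

  # identical points cannot be split
  same <- fake_embedding(matrix(1, 40, 2,
                                dimnames = list(sprintf("c%03d", 1:40), NULL)))
  cl2 <- cluster_node(norm[, 1:40], same, 1:40, cfg)
  expect_true(cl2$unsplittable)
})

test_that("community detection agrees with exhaustive modularity maximization", {
  # all set partitions of n elements (restricted growth strings)
  partitions <- function(n) {
    out <- list()
    rec <- function(prefix, maxv) {
      k <- length(prefix)
      if (k == n) {
        out[[length(out) + 1L]] <<- prefix
        return()
      }
      for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
    }
    rec(integer(), 0L)
    out
  }
  set.seed(14)
  coords <- rbind(matrix(rnorm(4 * 2, sd = 0.3), 4, 2),
                  matrix(rnorm(4 * 2, mean = 6, sd = 0.3), 4, 2))
  rownames(coords) <- sprintf("c%d", 1:8)
  g <- tierclust:::.snn_graph(coords, k = 3)
  best <- -Inf
  best_part <- NULL
  for (p in partitions(8)) {
    q <- igraph::modularity(g, p, weights = igraph::E(g)$weight)
    if (q > best + 1e-12) {
      best <- q
      best_part <- p
    }
  }
  norm <- Matrix::Matrix(matrix(1, 3, 8, dimnames = list(letters[1:3],
                                                         rownames(coords))),
                         sparse = TRUE)
  cl <- cluster_node(norm, fake_embedding(coords), 1:8,
                     clustering_config(local_embed = FALSE,
                                       resolutions = 1, knn_k = 3, seed = 1))
  expect_equal(ari(cl$labels, best_part), 1)
})

test_that("tier recovery: nested scene yields the true tree and labels", {
  scene <- std_scene()
  tree <- run_tiered_clustering(std_norm(), std_emb(), clustering_config(seed = 1))
  expect_true(is_nested_topology(tree$cell_labels))
  expect_equal(ari(tree$cell_labels, scene$truth$tier_path), 1)
  # the soma branch is the nested one
  term <- as.data.frame(tree)
  expect_equal(length(unique(term$terminal_label)), 3)
})

test_that("tier trees satisfy the partition and prefix invariants", {
  tree <- run_tiered_clustering(std_norm(), std_emb(), clustering_config(seed = 1))
  nd <- tree$nodes
  # children partition their parent
  for (p in nd$label[!nd$terminal]) {
    kids <- nd[!is.na(nd$parent) & nd$parent == p, ]
    expect_equal(sum(kids$n_cells), nd$n_cells[nd$label == p])
  }
  # every cell's tier-k label is a prefix of its terminal label
  tab <- as.data.frame(tree)
  for (k in seq_len(max(nd$depth) - 1)) {
    col <- paste0("tier", k)
    expect_true(all(startsWith(tab$terminal_label, tab[[col]])))
  }
  # terminal labels cover all cells exactly once
  expect_equal(sum(nd$n_cells[nd$terminal]), length(tree$cell_labels))
  expect_false(anyNA(tree$cell_labels))
})

test_that("tiered clustering is deterministic for a fixed config and seed", {
  cfg <- clustering_config(seed = 5)
  t1 <- run_tiered_clustering(std_norm(), std_emb(), cfg)
  t2 <- run_tiered_clustering(std_norm(), std_emb(), cfg)
  expect_identical(t1$cell_labels, t2$cell_labels)
  expect_identical(t1$nodes, t2$nodes)
})

test_that("a homogeneous population stays a single terminal cluster", {
  singles <- vapply(1:10, function(s) {
    scene <- homogeneous_scene(400, 1000, seed = s)
    norm <- normalize_log_cp10k(scene$counts)
    emb <- embed_pca(norm, select_variable_genes(norm, 500), 20)
    tree <- run_tiered_clustering(norm, emb, clustering_config(seed = 1))
    identical(unique(unname(tree$cell_labels)), "0")
  }, logical(1))
  expect_gte(sum(singles), 9)
})

test_that("supervised marker splits isolate rare planted subtypes", {
  scene <- homogeneous_scene(400, 600, seed = 17)
  rare <- sample(colnames(scene$counts), 20)
  scene$counts["G000001", rare] <- scene$counts["G000001", rare] + 50
  norm <- normalize_log_cp10k(scene$counts)
  emb <- embed_pca(norm, select_variable_genes(norm, 300), 20)
  tree <- run_tiered_clustering(norm, emb, clustering_config(seed = 1))
  node <- unique(unname(tree$cell_labels))[1]

  expect_error(split_cluster_by_marker(tree, norm, "9.9", "G000001", 1),
               "does not exist")
  split <- split_cluster_by_marker(tree, norm, node, "G000001", 1)
  child_of_rare <- unique(split$cell_labels[rare])
  expect_length(child_of_rare, 1)
  in_child <- names(split$cell_labels)[split$cell_labels == child_of_rare]
  expect_gte(mean(rare %in% in_child), 0.95)
  expect_true(all(split$nodes$supervised[split$nodes$parent %in% node]))
  # splitting a non-terminal node is refused
  expect_error(split_cluster_by_marker(split, norm, node, "G000001", 1),
               "not terminal")
  # threshold putting all cells on one side: warned no-op
  expect_warning(out <- split_cluster_by_marker(tree, norm, node, "G000001", 0),
                 "one side")
  expect_identical(out$cell_labels, tree$cell_labels)
})

test_that("tier tables and JSON serialization expose the fitted tree", {
  tree <- run_tiered_clustering(std_norm(), std_emb(), clustering_config(seed = 1))
  tab <- as.data.frame(tree)
  expect_setequal(names(tab), c("cell_id", "tier1", "tier2", "terminal_label"))
  expect_equal(nrow(tab), 900)
  js <- tier_tree_json(tree)
  parsed <- jsonlite::fromJSON(js)
  expect_setequal(parsed$nodes$label, tree$nodes$label)
  expect_output(print(tree), "terminal clusters")
  expect_output(summary(tree), "Gate decisions")
})
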