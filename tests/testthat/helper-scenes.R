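# Shared fixtures, built in code and cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# the standard nested scene: germ leaf + soma branch splitting in two,
# 300 cells/leaf, 50 markers/node, fold 8, 3 batches
std_scene <- function(seed = 1) {
  cached(paste0("std", seed), simulate_counts(example_hierarchy_spec(seed = seed)))
}

std_norm <- function(seed = 1) {
  cached(paste0("stdnorm", seed), normalize_log_cp10k(std_scene(seed)$counts))
}

std_emb <- function(seed = 1) {
  cached(paste0("stdemb", seed), {
    norm <- std_norm(seed)
    correct_batches(embed_pca(norm, select_variable_genes(norm, 1000), 30),
                    std_scene(seed)$truth$batch)
  })
}

# a single homogeneous negative-binomial population
homogeneous_scene <- function(n_cells, n_genes, seed) {
  nodes <- data.frame(name = c("root", "a"), parent = c(NA, "root"),
                      n_cells = c(0, n_cells))
  simulate_counts(hierarchy_spec(nodes, n_genes = n_genes, n_batches = 1,
                                 batch_sigma = 0, seed = seed))
}

# hand-made embedding object around a coordinate matrix
fake_embedding <- function(coords) {
  structure(list(coords = coords, var_share = rep(NA_real_, ncol(coords)),
                 eig = NULL, n_cells = nrow(coords),
                 loadings = NULL, genes = character()),
            class = "embedding")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# terminal labels form a nested two-lineage topology: one singleton tier-1
# label plus one tier-1 label with exactly two children
is_nested_topology <- function(terminal_labels) {
  labs <- sort(unique(terminal_labels))
  if (length(labs) != 3L) return(FALSE)
  depth <- lengths(strsplit(labs, ".", fixed = TRUE))
  if (!setequal(depth, c(1L, 2L)) || sum(depth == 1L) != 1L) return(FALSE)
  kids <- labs[depth == 2L]
  length(unique(sub("\\.[0-9]+$", "", kids))) == 1L
}
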