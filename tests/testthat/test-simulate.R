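test_that("identical spec and seed give bit-identical scenes", {
  nodes <- data.frame(name = c("root", "a"), parent = c(NA, "root"),
                      n_cells = c(0, 60))
  spec <- hierarchy_spec(nodes, n_genes = 300, markers_per_node = 10, seed = 7)
  s1 <- simulate_counts(spec)
  s2 <- simulate_counts(spec)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)

  g1 <- simulate_gradient(gradient_spec(n_cells = 80, n_genes = 200, seed = 3))
  g2 <- simulate_gradient(gradient_spec(n_cells = 80, n_genes = 200, seed = 3))
  expect_identical(g1$counts, g2$counts)
  expect_identical(g1$truth$t, g2$truth$t)
})

test_that("counts are non-negative integers and respect batch structure", {
  scene <- std_scene()
  x <- scene$counts@x
  expect_true(all(x >= 0))
  expect_identical(x, round(x))
  expect_setequal(unique(scene$truth$batch), 1:3)
  # 300 cells per leaf, split across the 3 batches
  expect_equal(unname(table(scene$truth$tier_path)),
               c(300, 300, 300), ignore_attr = TRUE)
  expect_identical(colnames(scene$counts), scene$truth$cell_id)
})

test_that("fold change 1 plants no detectable marker signal", {
  nodes <- data.frame(name = c("root", "a", "b"), parent = c(NA, "root", "root"),
                      n_cells = c(0, 150, 150))
  spec <- hierarchy_spec(nodes, markers_per_node = 50, marker_fold_change = 1,
                         n_genes = 600, n_batches = 1, batch_sigma = 0, seed = 5)
  scene <- simulate_counts(spec)
  ina <- scene$truth$tier_path == "a"
  pvals <- vapply(c(scene$markers$a, scene$markers$b), function(g) {
    stats::t.test(as.numeric(scene$counts[g, ina]),
                  as.numeric(scene$counts[g, !ina]))$p.value
  }, numeric(1))
  expect_gte(mean(pvals >= 0.01), 0.95)
})

test_that("realized marker elevation matches the negative-binomial expectation", {
  nodes <- data.frame(name = c("root", "a", "b", "c"),
                      parent = c(NA, "root", "root", "root"),
                      n_cells = c(0, 300, 300, 300))
  spec <- hierarchy_spec(nodes, markers_per_node = 50, marker_fold_change = 8,
                         n_batches = 1, batch_sigma = 0, seed = 11)
  scene <- simulate_counts(spec)
  for (leaf in c("a", "b", "c")) {
    m <- scene$markers[[leaf]]
    ins <- scene$truth$tier_path == leaf
    ratio <- mean(Matrix::rowMeans(scene$counts[m, ins])) /
      mean(Matrix::rowMeans(scene$counts[m, !ins]))
    # per-cell renormalisation to the library size damps the nominal fold
    expect_gt(ratio, 8 * 0.75)
    expect_lt(ratio, 8 * 1.25)
  }
})

test_that("marker planting is hierarchical across descendant leaves", {
  scene <- std_scene()
  soma_markers <- scene$markers$soma
  mean_in <- function(path) {
    mean(Matrix::rowMeans(scene$counts[soma_markers,
                                       scene$truth$tier_path == path]))
  }
  expect_gt(mean_in("soma/somaA"), 3 * mean_in("germ"))
  expect_gt(mean_in("soma/somaB"), 3 * mean_in("germ"))
})

test_that("invalid hierarchy specifications are rejected", {
  nodes <- data.frame(name = c("root", "a"), parent = c(NA, "root"),
                      n_cells = c(0, 10))
  expect_error(hierarchy_spec(nodes, markers_per_node = 60, n_genes = 50),
               "marker genes")
  expect_error(hierarchy_spec(rbind(nodes, data.frame(
    name = "b", parent = "zzz", n_cells = 5))), "unknown parent")
  expect_error(hierarchy_spec(nodes, marker_fold_change = 0.5), ">= 1")
})

test_that("doublet injection appends the requested number of labelled doublets", {
  scene <- std_scene()
  expect_identical(inject_doublets(scene, 0)$counts, scene$counts)

  dbl <- inject_doublets(scene, 0.05, seed = 2)
  expect_equal(sum(dbl$truth$is_doublet), round(0.05 * 900))
  expect_equal(ncol(dbl$counts), 900 + 45)
  # doublet parents come from distinct tier-1 branches
  d <- dbl$truth[dbl$truth$is_doublet, ]
  t1 <- function(id) {
    sub("/.*", "", dbl$truth$tier_path[match(id, dbl$truth$cell_id)])
  }
  expect_true(all(t1(d$parent_a) != t1(d$parent_b)))
  expect_error(inject_doublets(scene, 1.2), "rate")
})

test_that("doublet library sizes follow the singlet distribution", {
  dbl_tot <- c()
  sng_tot <- c()
  for (s in 1:20) {
    scene <- homogeneous_scene(100, 300, seed = s)
    # give it two branches by relabelling half the cells
    scene$truth$tier_path[1:50] <- "b"
    dbl <- inject_doublets(scene, 0.3, seed = s + 50)
    tot <- Matrix::colSums(dbl$counts)
    dbl_tot <- c(dbl_tot, tot[dbl$truth$is_doublet])
    sng_tot <- c(sng_tot, tot[!dbl$truth$is_doublet])
  }
  se <- stats::sd(sng_tot) / sqrt(length(dbl_tot))
  expect_lt(abs(mean(dbl_tot) - mean(sng_tot)), 2 * se)
})

test_that("gradient genes respond monotonically to latent position", {
  g <- simulate_gradient(gradient_spec(seed = 4))
  up <- sprintf("G%06d",
                g$spec$monotone_genes$gene[g$spec$monotone_genes$direction == "up"][1])
  dn <- sprintf("G%06d",
                g$spec$monotone_genes$gene[g$spec$monotone_genes$direction == "down"][1])
  ct_up <- stats::cor.test(as.numeric(g$counts[up, ]), g$truth$t,
                           method = "spearman", exact = FALSE)
  ct_dn <- stats::cor.test(as.numeric(g$counts[dn, ]), g$truth$t,
                           method = "spearman", exact = FALSE)
  expect_gt(ct_up$estimate, 0)
  expect_lt(ct_up$p.value, 1e-6)
  expect_lt(ct_dn$estimate, 0)
  expect_error(gradient_spec(n_up = 0, n_down = 0), "monotone")
})

test_that("vanishing amplitude leaves no rank correlation", {
  rhos <- vapply(1:10, function(s) {
    g <- simulate_gradient(gradient_spec(n_genes = 300, amplitude = 1e-6,
                                         n_up = 5, n_down = 5, seed = s))
    up <- sprintf("G%06d", g$spec$monotone_genes$gene[1])
    abs(stats::cor(as.numeric(g$counts[up, ]), g$truth$t, method = "spearman"))
  }, numeric(1))
  expect_gte(mean(rhos < 0.1), 0.9)
})

test_that("scenes combine over a shared gene space", {
  a <- std_scene()
  g <- simulate_gradient(gradient_spec(n_genes = 2000, seed = 9))
  comb <- combine_scenes(a, g)
  expect_equal(ncol(comb$counts), ncol(a$counts) + ncol(g$counts))
  expect_identical(rownames(comb$counts), rownames(a$counts))
  expect_equal(sum(!is.na(comb$truth$t)), 500)

  small <- simulate_gradient(gradient_spec(n_genes = 100, n_up = 5,
                                           n_down = 5, seed = 9))
  expect_error(combine_scenes(a, small), "gene space")
  expect_error(gradient_spec(n_genes = 100, n_up = 120, n_down = 0),
               "out of range")
})
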