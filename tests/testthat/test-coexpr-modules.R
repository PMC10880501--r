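test_that("variable gene selection matches a brute-force variance sort", {
  m <- tiny_counts(n_genes = 40, n_cells = 15, seed = 1, mito = FALSE)
  nm <- normalize_counts(m)
  sel <- select_variable_genes(nm, 10)
  v <- apply(nm$values, 1, var)
  ref <- names(sort(v, decreasing = TRUE))[1:10]
  expect_setequal(sel, ref)
  # full selection is the identity set; over-asking warns
  expect_setequal(select_variable_genes(nm, nrow(nm$values)), rownames(nm$values))
  expect_warning(select_variable_genes(nm, 1000), "exceeds")
  # constant genes rank last
  x <- nm$values
  x[1, ] <- 5
  nm2 <- pathtriage:::new_normalized_matrix(x, 1e4, dim(x))
  expect_false(rownames(x)[1] %in%
                 select_variable_genes(nm2, nrow(x) - 1))
})

test_that("scale-free fit recognises a power-law degree sequence", {
  # frequency ~ k^-1.5 by construction
  vals <- 2^(seq(0, 7, by = 0.5))
  counts <- round(2000 * vals^-1.5)
  k <- rep(vals, counts)
  fit <- pathtriage:::scale_free_fit(k, n_bins = 10)
  expect_gt(fit$r_squared, 0.9)
  expect_lt(fit$slope, 0)
  # uncorrelated data: low signed fit, fallback path taken with warning
  S <- diag(50)
  S[upper.tri(S)] <- S[lower.tri(S)] <- 0.01
  expect_warning(res <- soft_threshold_scan(S, powers = 1:5),
                 "no power reached")
  expect_true(res$beta %in% 1:5)
  # degenerate all-equal connectivity
  expect_equal(pathtriage:::scale_free_fit(rep(3, 10))$r_squared, 0)
})

test_that("adjacency is the elementwise soft power", {
  expect_equal(adjacency_matrix(matrix(0.5), 2), matrix(0.25))
  set.seed(2)
  S <- cor(matrix(rnorm(200), 20, 10))
  expect_equal(adjacency_matrix(S, 1), abs(S))
  expect_equal(adjacency_matrix(S, 7), abs(S)^7)
  expect_error(adjacency_matrix(S, 0))
})

test_that("tom matches the triple-loop oracle and stays in [0, 1]", {
  # two genes connected only to each other overlap perfectly
  A <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3)
  tom <- tom_similarity(A)
  expect_equal(tom[1, 2], 1)
  expect_equal(tom[1, 3], 0)  # no edge, no shared neighbours

  set.seed(3)
  for (i in 1:20) {
    S <- cor(matrix(rnorm(10 * 30), 30, 10))
    A <- abs(S)^3
    tom <- tom_similarity(A)
    expect_lt(max(abs(tom - oracle_tom(A))), 1e-12)
    expect_true(all(tom >= 0 - 1e-12 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("module detection recovers planted blocks and is label-stable", {
  set.seed(4)
  # planted-partition TOM: strong within-block, weak between
  n <- 60
  block <- rep(1:2, each = 30)
  tom <- matrix(runif(n * n, 0, 0.05), n)
  tom[block == 1, block == 1] <- runif(sum(block == 1)^2, 0.6, 0.9)
  tom[block == 2, block == 2] <- runif(sum(block == 2)^2, 0.6, 0.9)
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- paste0("g", 1:n)
  mods <- cluster_modules(1 - tom, min_module_size = 10, cut_height = 0.8)
  expect_setequal(unique(mods$module), c("M1", "M2"))
  expect_equal(length(unique(mods$module[block == 1])), 1)
  expect_equal(length(unique(mods$module[block == 2])), 1)

  # permuting gene order leaves module contents invariant
  perm <- sample(n)
  mods_p <- cluster_modules((1 - tom)[perm, perm], min_module_size = 10,
                            cut_height = 0.8)
  for (m in c("M1", "M2")) {
    orig <- sort(mods$gene[mods$module == m])
    matched <- sort(mods_p$gene[mods_p$module ==
                                  mods_p$module[mods_p$gene == orig[1]]])
    expect_identical(orig, matched)
  }

  # all-equal dissimilarities collapse deterministically to one module
  d0 <- matrix(0.5, 20, 20)
  diag(d0) <- 0
  rownames(d0) <- colnames(d0) <- paste0("g", 1:20)
  m0a <- cluster_modules(d0, min_module_size = 5, cut_height = 0.99)
  m0b <- cluster_modules(d0, min_module_size = 5, cut_height = 0.99)
  expect_identical(m0a, m0b)
  expect_equal(length(unique(m0a$module)), 1)
})

test_that("small clusters are merged into grey and labels follow size", {
  set.seed(5)
  n <- 50
  tom <- matrix(runif(n * n, 0, 0.05), n)
  tom[1:30, 1:30] <- runif(900, 0.7, 0.9)
  tom[31:45, 31:45] <- runif(225, 0.7, 0.9)
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- paste0("g", 1:n)
  mods <- cluster_modules(1 - tom, min_module_size = 10, cut_height = 0.8)
  expect_equal(unname(table(mods$module)[c("M1", "M2")]),
               c(30L, 15L), ignore_attr = TRUE)
  expect_true(all(mods$module[46:50] == "grey"))
})

test_that("eigengenes are unit norm and track their module", {
  sim <- sim_counts(small_config(seed = 1))
  nm <- normalize_counts(sim$counts)
  net <- coexpr_network(nm, n_genes = 300)
  mods <- cluster_modules(1 - net$tom)
  eg <- module_eigengenes(nm, mods)
  non_grey <- setdiff(names(eg), "cell")
  expect_gt(length(non_grey), 0)
  for (m in non_grey) {
    expect_equal(sum(eg[[m]]^2), 1)
    member <- mods$gene[mods$module == m][1]
    expect_gt(abs(cor(eg[[m]], nm$values[member, ])), 0.1)
  }
})

test_that("planted module is recovered and correlates with pathway genes", {
  jaccards <- best_hits <- numeric(5)
  for (s in 1:5) {
    sim <- sim_counts(sim_config(seed = s))
    nm <- normalize_counts(sim$counts)
    tn <- sim$counts$cell_meta$group %in% c("tumor", "normal")
    nm_tn <- pathtriage:::new_normalized_matrix(nm$values[, tn], 1e4, dim(nm$values))
    net <- coexpr_network(nm_tn, n_genes = 1000)
    mods <- cluster_modules(1 - net$tom)
    mpc <- module_pathway_correlation(nm_tn, mods, sim$truth$pathway_gene_ids,
                                      traits = NULL)
    planted <- sim$truth$module_gene_ids
    best <- mpc$best_module
    members <- mods$gene[mods$module == best]
    jaccards[s] <- length(intersect(members, planted)) /
      length(union(members, planted))
    best_hits[s] <- sim$truth$planted_regulator_id %in% members
  }
  expect_true(all(jaccards >= 0.8))
  expect_true(all(best_hits == 1))
})

test_that("module correlation handles constant traits and missing genes", {
  sim <- sim_counts(small_config(seed = 1))
  nm <- normalize_counts(sim$counts)
  net <- coexpr_network(nm, n_genes = 300)
  mods <- cluster_modules(1 - net$tom)
  expect_warning(
    mpc <- module_pathway_correlation(
      nm, mods, c(sim$truth$pathway_gene_ids, "NOT_A_GENE"),
      traits = tibble::tibble(flat = rep(1, ncol(nm$values)))
    ),
    "absent"
  )
  flat_rows <- dplyr::filter(mpc$correlations, variable == "flat")
  expect_true(all(is.na(flat_rows$r)))
})

test_that("network pipeline is equivariant to gene order", {
  m <- tiny_counts(n_genes = 30, n_cells = 25, seed = 9, mito = FALSE)
  nm <- normalize_counts(m)
  S <- cor(t(nm$values))
  set.seed(10)
  perm <- sample(nrow(S))
  A <- adjacency_matrix(S, 4)
  expect_equal(adjacency_matrix(S[perm, perm], 4), A[perm, perm])
  expect_equal(tom_similarity(A[perm, perm]),
               tom_similarity(A)[perm, perm])
})
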