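test_that("generators are deterministic for a fixed config", {
  cfg <- small_config(seed = 7)
  a <- sim_all(cfg)
  b <- sim_all(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$counts$cell_meta, b$counts$cell_meta)
  expect_identical(a$gene_sets$sets, b$gene_sets$sets)
  expect_identical(graph_edges(a$ppi), graph_edges(b$ppi))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$de_gene_ids, b$truth$de_gene_ids)
})

test_that("null config gives equal tumor/normal means and no planted signal", {
  cfg <- small_config(seed = 3, n_de_genes = 0, module_latent_sd = 0)
  sim <- sim_counts(cfg)
  expect_length(sim$truth$de_gene_ids, 0)
  grp <- sim$counts$cell_meta$group
  mt <- rowMeans(sim$counts$counts[, grp == "tumor"])
  mn <- rowMeans(sim$counts$counts[, grp == "normal"])
  keep <- mt > 0.5 & mn > 0.5
  # per-gene log mean-ratios centred on zero
  expect_lt(abs(mean(log(mt[keep] / mn[keep]))), 0.1)
})

test_that("planted DE genes carry the configured log fold change", {
  cfg <- sim_config(n_cells_per_group = 500, n_genes = 500, n_de_genes = 30,
                    de_logfc_mean = 1.0, n_module_genes = 50,
                    ppi_n_background_genes = 100, seed = 5)
  sim <- sim_counts(cfg)
  grp <- sim$counts$cell_meta$group
  de <- sim$truth$de_gene_ids
  ratio <- log(rowMeans(sim$counts$counts[de, grp == "tumor"]) /
                 rowMeans(sim$counts$counts[de, grp == "normal"]))
  expect_lt(abs(mean(ratio) - 1.0), 0.2)
})

test_that("mitochondrial content stays below the default QC threshold", {
  sim <- sim_counts(sim_config(seed = 2))
  qc <- compute_qc(sim$counts)
  expect_true(all(qc$percent_mt < 20))
  expect_gt(mean(qc$percent_mt), 2)  # mito genes are present, not trivial
})

test_that("downstream DE recovers planted genes across seeds", {
  hit_rates <- vapply(1:5, function(s) {
    sim <- sim_counts(sim_config(seed = s))
    nm <- normalize_counts(sim$counts)
    de <- wilcoxon_de(nm, sim$counts$cell_meta$group, "tumor", "normal")
    sig <- de$gene[de$p_val_adj < 0.05]
    mean(sim$truth$de_gene_ids %in% sig)
  }, numeric(1))
  expect_true(all(hit_rates >= 0.9))
})

test_that("gene sets contain the planted pathway and honest decoys", {
  cfg <- small_config(seed = 9)
  sim <- sim_counts(cfg)
  gs <- sim_gene_sets(cfg, sim$truth)
  expect_setequal(gs$sets[["PATHWAY_AKT"]], sim$truth$pathway_gene_ids)
  decoys <- gs$sets[names(gs$sets) != "PATHWAY_AKT"]
  expect_true(all(vapply(decoys, function(s) !setequal(s, gs$sets[["PATHWAY_AKT"]]),
                         logical(1))))
  expect_true(all(vapply(decoys, function(s) !anyDuplicated(s), logical(1))))
  # serialized GMT is byte-identical under a fixed seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(sim_gene_sets(cfg, sim$truth), f1)
  write_gmt(sim_gene_sets(cfg, sim$truth), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ppi graph carries the planted regulator wiring", {
  cfg <- small_config(seed = 4)
  sim <- sim_counts(cfg)
  g <- sim_ppi(cfg, sim$truth)
  partners <- direct_partners(g, sim$truth$planted_regulator_id)
  expect_gte(sum(partners %in% sim$truth$pathway_gene_ids),
             cfg$regulator_direct_targets)
  # with zero background probability only planted edges remain
  g0 <- sim_ppi(small_config(seed = 4, ppi_edge_prob = 0), sim$truth)
  e0 <- graph_edges(g0)
  in_planted <- (e0$gene_a %in% c(sim$truth$pathway_gene_ids, "MDFI")) &
    (e0$gene_b %in% c(sim$truth$pathway_gene_ids, "MDFI"))
  expect_true(all(in_planted))
})

test_that("background edge count matches the binomial expectation", {
  cfg <- sim_config(n_genes = 600, n_cells_per_group = 10, n_de_genes = 20,
                    n_module_genes = 40, ppi_n_background_genes = 446,
                    ppi_edge_prob = 0.01, seed = 8)
  sim <- sim_counts(cfg)
  g <- sim_ppi(cfg, sim$truth)
  n <- igraph::vcount(g$graph)
  m <- igraph::ecount(g$graph)
  n_pairs <- n * (n - 1) / 2
  expected <- n_pairs * cfg$ppi_edge_prob
  sd_m <- sqrt(n_pairs * cfg$ppi_edge_prob * (1 - cfg$ppi_edge_prob))
  n_planted <- cfg$n_pathway_genes + cfg$regulator_direct_targets
  expect_lt(abs(m - expected), 3 * sd_m + n_planted)
})

test_that("clinical generator reproduces the exact contingency table", {
  cfg <- sim_config(seed = 6)
  truth <- sim_counts(small_config())$truth
  ct <- sim_clinical(cfg, truth)
  expect_equal(nrow(ct), 260)
  high <- ct$marker_expression > median(ct$marker_expression)
  tab <- c(sum(high & ct$histology_positive == 1),
           sum(high & ct$histology_positive == 0),
           sum(!high & ct$histology_positive == 1),
           sum(!high & ct$histology_positive == 0))
  expect_identical(tab, c(66L, 64L, 45L, 85L))
})

test_that("clinical generator validates its configuration", {
  truth <- sim_counts(small_config())$truth
  expect_error(sim_clinical(sim_config(clinical_n = 0), truth),
               class = "pathtriage_config_error")
  expect_error(
    sim_clinical(sim_config(clinical_n = 100), truth,
                 exact_contingency = TRUE),
    class = "pathtriage_config_error"
  )
  # odds-ratio mode still produces a positive association
  ct <- sim_clinical(sim_config(clinical_n = 2000, seed = 3), truth)
  high <- ct$marker_expression > median(ct$marker_expression)
  or <- (sum(high & ct$histology_positive == 1) *
           sum(!high & ct$histology_positive == 0)) /
    (sum(high & ct$histology_positive == 0) *
       sum(!high & ct$histology_positive == 1))
  expect_gt(or, 1)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_de_genes = 500, n_module_genes = 600,
                          n_genes = 1000),
               class = "pathtriage_config_error")
  expect_error(sim_config(regulator_direct_targets = 20, n_pathway_genes = 14),
               class = "pathtriage_config_error")
  expect_error(sim_config(nb_dispersion = 0), class = "pathtriage_config_error")
})
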