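#' Run the full regulator-triage pipeline
#'
#' Chains the stages end to end: per-cell QC and filtering, log
#' normalization, PCA, tumor-versus-normal Wilcoxon differential
#' expression, enrichment (ORA on the significant genes and permutation
#' GSEA on the log-fold-change ranking), weighted co-expression network and
#' module detection on the tumor and normal cells, module-pathway/trait
#' correlation to pick the candidate module, PPI level-count ranking of the
#' module genes against the enrichment-confirmed pathway genes, and the
#' clinical validation statistics. The same config plus seed always yields
#' the identical report.
#'
#' @param config A [sim_config()] describing the synthetic inputs (also
#'   supplies the seed for the GSEA permutation null).
#' @param inputs Optional pre-built inputs as returned by [sim_all()] (a
#'   list with `counts`, `gene_sets`, `ppi`, `clinical`, optionally
#'   `truth`); when `NULL` they are generated from `config`.
#' @param max_percent_mt QC threshold (percent, strict).
#' @param min_pct,min_abs_logfc Differential-expression screens.
#' @param n_perm GSEA permutations.
#' @param n_variable_genes Genes entering the co-expression network.
#' @param powers,target_r2 Soft-threshold scan settings.
#' @param min_module_size,cut_height Module detection settings.
#' @param candidates Optional override of the PPI candidate genes (default:
#'   the genes of the best-correlated module).
#' @param targets Optional override of the PPI target genes (default: the
#'   members of the most significantly enriched gene set).
#' @param run_pca Whether to compute the PCA embedding (reported only).
#' @return A `triage_report` list with elements `qc`, `pca_sdev`, `de`,
#'   `ora`, `gsea`, `network` (beta + scale-free profile), `modules`,
#'   `module_correlations`, `best_module`, `ranking`, `clinical`, and
#'   `provenance`.
#' @examples
#' \donttest{
#' rep <- run_triage(sim_config(n_genes = 300, n_cells_per_group = 60,
#'                              n_de_genes = 20, n_module_genes = 40,
#'                              ppi_n_background_genes = 100))
#' rep$ranking[1, ]
#' }
#' @export
run_triage <- function(config = sim_config(), inputs = NULL,
                       max_percent_mt = 20, min_pct = 0.25,
                       min_abs_logfc = 0.25, n_perm = 1000,
                       n_variable_genes = 5000, powers = 1:20,
                       target_r2 = 0.85, min_module_size = 30,
                       cut_height = 0.99, candidates = NULL,
                       targets = NULL, run_pca = TRUE) {
  config <- validate_sim_config(config)
  if (is.null(inputs)) inputs <- sim_all(config)
  for (need in c("counts", "gene_sets", "ppi", "clinical")) {
    if (is.null(inputs[[need]]))
      abort(sprintf("pipeline stage 'inputs': missing '%s'", need),
            class = "pathtriage_input_error")
  }

  # --- QC ---------------------------------------------------------------
  qc <- compute_qc(inputs$counts)
  filtered <- filter_cells(inputs$counts, qc, max_percent_mt = max_percent_mt)
  nm <- normalize_counts(filtered)
  pca_sdev <- NULL
  if (run_pca) {
    pca <- scale_and_pca(nm, n_components = min(30, ncol(nm$values) - 1))
    pca_sdev <- pca$sdev
  }

  # --- Differential expression -----------------------------------------
  labels <- filtered$cell_meta$group
  de <- wilcoxon_de(nm, labels, "tumor", "normal",
                    min_pct = min_pct, min_abs_logfc = min_abs_logfc)
  if (nrow(de) == 0)
    warn("pipeline stage 'diff_expr': no gene passed the screens")

  # --- Enrichment -------------------------------------------------------
  universe <- rownames(nm$values)
  hits <- de$gene[de$p_val_adj < 0.05]
  ora <- if (length(hits) > 0)
    ora_hypergeometric(hits, universe, inputs$gene_sets)
  else tibble(set_name = character(), set_size = integer(),
              k_overlap = integer(), p = numeric(), q = numeric(),
              overlap_genes = list())
  # ranking metric: signed avg_logFC over all genes (no detection screen,
  # so every gene-set member is rankable); ties broken by gene symbol
  m1 <- labels == "tumor"
  m2 <- labels == "normal"
  lfc_all <- log(rowMeans(expm1(nm$values[, m1, drop = FALSE])) + 1) -
    log(rowMeans(expm1(nm$values[, m2, drop = FALSE])) + 1)
  ranked <- dplyr::arrange(
    tibble(gene = rownames(nm$values), score = lfc_all),
    dplyr::desc(.data$score), .data$gene
  )
  gsea_res <- gsea(ranked, inputs$gene_sets, n_perm = n_perm,
                   seed = config$seed)
  if (is.null(targets)) {
    if (nrow(gsea_res) == 0)
      abort("pipeline stage 'enrichment': no scorable gene set",
            class = "pathtriage_stage_error")
    top_set <- gsea_res$set_name[1]
    targets <- inputs$gene_sets$sets[[top_set]]
  } else {
    top_set <- NA_character_
  }

  # --- Co-expression network on tumor + normal cells --------------------
  tn <- filtered$cell_meta$group %in% c("tumor", "normal")
  nm_tn <- new_normalized_matrix(nm$values[, tn, drop = FALSE],
                                 nm$scale_factor, dim(nm$values))
  net <- coexpr_network(nm_tn,
                        n_genes = min(n_variable_genes, nrow(nm$values)),
                        powers = powers, target_r2 = target_r2)
  modules <- cluster_modules(1 - net$tom, min_module_size = min_module_size,
                             cut_height = cut_height)
  traits <- tibble(tumor = as.numeric(filtered$cell_meta$group[tn] == "tumor"))
  if ("stage_proxy" %in% names(filtered$cell_meta))
    traits$stage_proxy <- filtered$cell_meta$stage_proxy[tn]
  mpc <- module_pathway_correlation(nm_tn, modules, targets, traits)

  # --- PPI level ranking ------------------------------------------------
  if (is.null(candidates)) {
    if (is.na(mpc$best_module)) {
      warn("pipeline stage 'coexpr_modules': no module detected; ranking skipped")
      candidates <- character(0)
    } else {
      candidates <- modules$gene[modules$module == mpc$best_module]
    }
  }
  ranking <- if (length(candidates) > 0)
    rank_candidates(inputs$ppi, candidates, targets)
  else tibble(gene = character(), level1 = integer(), level2 = integer(),
              level3 = integer(), total = integer(), rank = integer())
  top_gene <- if (nrow(ranking) > 0) ranking$gene[1] else NA_character_

  # --- Clinical validation ---------------------------------------------
  ct <- inputs$clinical
  high <- ct$marker_expression > median(ct$marker_expression)
  cont <- matrix(
    c(sum(high & ct$histology_positive == 1),
      sum(high & ct$histology_positive == 0),
      sum(!high & ct$histology_positive == 1),
      sum(!high & ct$histology_positive == 0)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("marker_high", "marker_low"),
                    c("positive", "negative"))
  )
  clinical <- list(
    os = km_logrank(ct, "OS"),
    dfs = km_logrank(ct, "DFS"),
    contingency = cont,
    chisq = chisq_2x2(cont),
    stage = stage_association(ct),
    roc = roc_auc(ct$marker_expression, ct$chemo)
  )

  structure(
    list(
      qc = qc,
      pca_sdev = pca_sdev,
      de = de,
      ora = ora,
      gsea = gsea_res,
      network = list(beta = net$beta, profile = net$profile),
      modules = modules,
      module_correlations = mpc$correlations,
      best_module = mpc$best_module,
      top_set = top_set,
      ranking = ranking,
      top_gene = top_gene,
      clinical = clinical,
      provenance = list(
        config = unclass(config),
        n_cells_kept = ncol(filtered$counts),
        n_genes_tested = nrow(de),
        config_hash = rlang::hash(unclass(config))
      )
    ),
    class = "triage_report"
  )
}

#' @export
print.triage_report <- function(x, ...) {
  cat("<triage_report>\n")
  cat(sprintf("  cells kept: %d; DE genes tested: %d (%d at adj p < 0.05)\n",
              x$provenance$n_cells_kept, nrow(x$de),
              sum(x$de$p_val_adj < 0.05)))
  if (nrow(x$gsea) > 0)
    cat(sprintf("  top enriched set: %s (NES %.2f, q = %.3g)\n",
                x$gsea$set_name[1], x$gsea$nes[1], x$gsea$q[1]))
  cat(sprintf("  soft threshold beta = %d; best module: %s (%d genes)\n",
              x$network$beta, x$best_module,
              sum(x$modules$module %in% x$best_module)))
  if (nrow(x$ranking) > 0)
    cat(sprintf("  top-ranked candidate: %s (levels %d/%d/%d, total %d)\n",
                x$ranking$gene[1], x$ranking$level1[1], x$ranking$level2[1],
                x$ranking$level3[1], x$ranking$total[1]))
  cat(sprintf("  clinical: OS log-rank p = %.3g; chi^2 = %.3f (p = %.3g); AUC = %.3f\n",
              x$clinical$os$test$p, x$clinical$chisq$chi_square,
              x$clinical$chisq$p, x$clinical$roc$auc))
  invisible(x)
}

#' Write a triage report to disk
#'
#' Emits a machine-readable JSON summary and the stage tables as TSV files.
#'
#' @param report A `triage_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "triage_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$de, file.path(dir, "diff_expr.tsv"))
  readr::write_tsv(dplyr::select(report$gsea, -"leading_edge"),
                   file.path(dir, "gsea.tsv"))
  readr::write_tsv(report$modules, file.path(dir, "modules.tsv"))
  readr::write_tsv(report$network$profile, file.path(dir, "scale_free.tsv"))
  readr::write_tsv(report$ranking, file.path(dir, "ppi_ranking.tsv"))
  readr::write_csv(report$qc, file.path(dir, "qc_metrics.csv"))
  readr::write_tsv(report$module_correlations,
                   file.path(dir, "module_trait_correlation.tsv"))
  if (nrow(report$ora) > 0)
    readr::write_tsv(dplyr::select(report$ora, -"overlap_genes"),
                     file.path(dir, "ora.tsv"))
  jsonlite::write_json(
    list(
      top_gene = report$top_gene,
      best_module = report$best_module,
      top_set = report$top_set,
      beta = report$network$beta,
      n_de_significant = sum(report$de$p_val_adj < 0.05),
      clinical = list(
        os_logrank_p = report$clinical$os$test$p,
        dfs_logrank_p = report$clinical$dfs$test$p,
        chi_square = report$clinical$chisq$chi_square,
        chi_square_p = report$clinical$chisq$p,
        auc = report$clinical$roc$auc
      ),
      provenance = report$provenance
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
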