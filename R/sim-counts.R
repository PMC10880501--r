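#' Simulate a single-cell count matrix with planted signal
#'
#' Draws negative binomial counts for three cell groups (tumor, normal,
#' border) with three planted structures: (i) a DE gene set whose mean is
#' up-shifted in tumor cells by `de_logfc_mean` natural-log units (the
#' pathway genes are the first members of that set, so the target pathway is
#' genuinely overexpressed in tumor); (ii) a co-expression module whose genes
#' — plus a `pathway_module_share` fraction of the pathway genes — load on a
#' shared per-cell latent factor on the log-mean scale; (iii) a small block
#' of mitochondrial-tagged genes (`MT-` prefix) whose aggregate abundance is
#' calibrated to about 8% of each cell's library, so all cells pass the
#' default 20% QC threshold.
#'
#' The planted regulator (named `MDFI`) is a member of the co-expression
#' module; it carries no direct DE shift of its own. Per-cell library sizes
#' are log-normal around `library_size_mean`. Gene relative abundances are
#' renormalised per cell, so planting DE genes slightly deflates the
#' remaining genes, as in real compositional count data.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()], whose
#'   `cell_meta` carries a numeric `stage_proxy` trait correlated with the
#'   latent factor) and `truth` (a `ground_truth` list: `de_gene_ids`,
#'   `module_gene_ids`, `pathway_gene_ids`, `planted_regulator_id`,
#'   `latent_factor`).
#' @examples
#' sim <- sim_counts(sim_config(n_genes = 120, n_cells_per_group = 20,
#'                              n_de_genes = 14, n_module_genes = 20,
#'                              ppi_n_background_genes = 50))
#' dim(sim$counts)
#' @export
sim_counts <- function(config) {
  config <- validate_sim_config(config)
  nms <- sim_gene_names(config)
  set.seed(sim_substream_seed(config, "counts"))

  genes <- nms$genes
  n_genes <- config$n_genes
  groups <- rep(c("tumor", "normal", "border"), each = config$n_cells_per_group)
  n_cells <- length(groups)
  cells <- sprintf("CELL%05d", seq_len(n_cells))
  samples <- paste0("P", ((seq_len(n_cells) - 1L) %% 2L) + 1L, "_",
                    substr(groups, 1, 1))

  base <- rnorm(n_genes, 0, 1)
  names(base) <- genes

  # the latent cell-state factor moves loaded genes along two anticorrelated
  # arms (bipolar loadings); the unsigned network sees them as one module
  latent <- rnorm(n_cells, 0, 1)
  loading <- setNames(numeric(n_genes), genes)
  loaded <- character(0)
  if (config$module_latent_sd > 0) {
    loaded <- c(nms$module, nms$pathway_shared)
    loading[loaded] <- sample(c(-1, 1), length(loaded), replace = TRUE) *
      runif(length(loaded), 0.5, 1) * config$module_latent_sd
  }

  # calibrate mitochondrial genes to ~8% of the library in expectation
  if (length(nms$mito) > 0) {
    w <- exp(base)
    mito_share <- 0.08
    w_mt_target <- mito_share / (1 - mito_share) *
      sum(w[setdiff(genes, nms$mito)])
    base[nms$mito] <- base[nms$mito] + log(w_mt_target / sum(w[nms$mito]))
  }

  lfc <- setNames(numeric(n_genes), genes)
  lfc[nms$de] <- config$de_logfc_mean

  lib <- exp(rnorm(n_cells, log(config$library_size_mean), 0.3))
  tumor_ind <- as.numeric(groups == "tumor")
  log_mu <- matrix(base, n_genes, n_cells, dimnames = list(genes, cells)) +
    outer(loading, latent) +
    outer(lfc, tumor_ind)
  mu <- exp(log_mu)
  # hold the loaded genes' aggregate expression budget fixed per cell, so
  # the cell-state factor redistributes within the program instead of
  # inflating the library and coupling every other gene compositionally
  if (length(loaded) > 1) {
    s0 <- colSums(exp(matrix(base[loaded], length(loaded), n_cells) +
                        outer(lfc[loaded], tumor_ind)))
    sc <- colSums(mu[loaded, , drop = FALSE])
    mu[loaded, ] <- sweep(mu[loaded, , drop = FALSE], 2, s0 / sc, "*")
  }
  mu <- sweep(mu, 2, colSums(mu), "/")
  mu <- sweep(mu, 2, lib, "*")

  counts <- matrix(
    rnbinom(n_genes * n_cells, mu = mu, size = 1 / config$nb_dispersion),
    nrow = n_genes, ncol = n_cells,
    dimnames = list(genes, cells)
  )

  cell_meta <- tibble(
    cell = cells, sample = samples, group = groups,
    stage_proxy = latent + rnorm(n_cells, 0, 1)
  )

  truth <- structure(
    list(
      de_gene_ids = nms$de,
      module_gene_ids = nms$module,
      pathway_gene_ids = nms$pathway,
      planted_regulator_id = nms$regulator,
      latent_factor = setNames(latent, cells)
    ),
    class = "ground_truth"
  )
  list(counts = count_matrix(counts, cell_meta), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d DE genes, %d module genes, %d pathway genes; regulator %s\n",
    length(x$de_gene_ids), length(x$module_gene_ids),
    length(x$pathway_gene_ids), x$planted_regulator_id
  ))
  invisible(x)
}

# Deterministic gene-name layout shared by the generators:
# regulator + module genes, pathway genes, extra DE genes, mitochondrial
# decoys, then background filler. Pathway genes double as the leading DE
# genes whenever n_de_genes > 0.
sim_gene_names <- function(config) {
  n_mito <- min(10L, max(0L, config$n_genes -
                           config$n_module_genes - config$n_pathway_genes -
                           max(config$n_de_genes - config$n_pathway_genes, 0L)))
  regulator <- "MDFI"
  module <- if (config$n_module_genes > 0)
    c(regulator, sprintf("MOD%03d", seq_len(config$n_module_genes - 1L)))
  else character()
  pathway <- if (config$n_pathway_genes <= length(pi3k_akt_symbols))
    pi3k_akt_symbols[seq_len(config$n_pathway_genes)]
  else
    sprintf("PATHWAY%02d", seq_len(config$n_pathway_genes))
  n_extra_de <- max(config$n_de_genes - config$n_pathway_genes, 0L)
  de_extra <- if (n_extra_de > 0) sprintf("DEG%03d", seq_len(n_extra_de)) else character()
  de <- if (config$n_de_genes > 0)
    c(pathway, de_extra)[seq_len(config$n_de_genes)]
  else character()
  mito <- if (n_mito > 0) paste0("MT-", seq_len(n_mito)) else character()
  named <- c(module, pathway, de_extra, mito)
  n_bg <- config$n_genes - length(named)
  if (n_bg < 0)
    abort("n_genes too small for the requested planted structures",
          class = "pathtriage_config_error")
  bg <- if (n_bg > 0) sprintf("GENE%04d", seq_len(n_bg)) else character()
  n_shared <- round(config$pathway_module_share * config$n_pathway_genes)
  list(
    genes = c(named, bg),
    regulator = regulator,
    module = module,
    pathway = pathway,
    pathway_shared = pathway[seq_len(n_shared)],
    de = de,
    mito = mito,
    background = bg
  )
}
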