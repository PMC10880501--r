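#' Simulation configuration for the synthetic triage inputs
#'
#' Bundles every tunable of the synthetic-data generators: the negative
#' binomial count model with a planted differentially expressed (DE) gene set
#' and a planted co-expression module, the gene-set collection, the
#' protein-protein interaction (PPI) graph with a planted regulator, and the
#' clinical table. One `seed` drives four independent sub-streams (counts,
#' gene sets, graph, clinical) so each generator can be re-run on its own and
#' still reproduce the same output.
#'
#' Defaults describe a desk-scale emulation of a tumor/normal/border
#' colorectal epithelial single-cell dataset: 400 cells per group, 1,000
#' genes, 50 DE genes up-shifted in tumor by one natural-log unit, a
#' 100-gene co-expression module driven by a shared per-cell latent factor,
#' a 14-gene target pathway whose members are named after canonical PI3K-AKT
#' genes, a sparse background interactome in which the pathway members
#' interact among themselves, and a 260-patient clinical table whose 2x2
#' histology cross-tabulation is (66, 64, 45, 85).
#'
#' @param n_cells_per_group Cells per group (groups are tumor, normal, border).
#' @param n_genes Total genes in the count matrix (including mitochondrial
#'   decoys and pathway genes).
#' @param n_de_genes Number of planted DE genes (includes the pathway genes).
#' @param de_logfc_mean Mean-scale natural-log fold change planted in tumor.
#' @param nb_dispersion Negative binomial dispersion phi (variance
#'   `mu + phi * mu^2`); must be > 0.
#' @param library_size_mean Mean per-cell library size (log-normal across cells).
#' @param n_module_genes Size of the planted co-expression module.
#' @param module_latent_sd Standard deviation of the per-gene latent-factor
#'   loadings on the log-mean scale; 0 disables co-expression.
#' @param n_pathway_genes Size of the planted pathway gene set (<= 14 reuses
#'   canonical PI3K-AKT symbols).
#' @param pathway_module_share Fraction of pathway genes that also load on the
#'   module's latent factor.
#' @param ppi_n_background_genes Background (decoy) nodes in the PPI graph.
#' @param ppi_edge_prob Erdos-Renyi edge probability of the background graph.
#' @param regulator_direct_targets Number of pathway genes wired directly to
#'   the planted regulator.
#' @param clinical_n Patients in the clinical table.
#' @param hazard_ratio_high_marker Hazard ratio applied to above-median marker
#'   expression in the survival generator.
#' @param contingency_counts Four non-negative integers (a, b, c, d) for the
#'   marker-high/low x histology-positive/negative 2x2 table; used exactly
#'   when their sum equals `clinical_n`.
#' @param seed Integer seed for all four generator sub-streams.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 200, n_cells_per_group = 50)
#' cfg$n_genes
#' @export
sim_config <- function(n_cells_per_group = 400,
                       n_genes = 1000,
                       n_de_genes = 50,
                       de_logfc_mean = 1.0,
                       nb_dispersion = 0.5,
                       library_size_mean = 5000,
                       n_module_genes = 100,
                       module_latent_sd = 2.0,
                       n_pathway_genes = 14,
                       pathway_module_share = 0.7,
                       ppi_n_background_genes = 500,
                       ppi_edge_prob = 0.005,
                       regulator_direct_targets = 5,
                       clinical_n = 260,
                       hazard_ratio_high_marker = 2.5,
                       contingency_counts = c(66, 64, 45, 85),
                       seed = 1L) {
  cfg <- list(
    n_cells_per_group = as.integer(n_cells_per_group),
    n_genes = as.integer(n_genes),
    n_de_genes = as.integer(n_de_genes),
    de_logfc_mean = as.numeric(de_logfc_mean),
    nb_dispersion = as.numeric(nb_dispersion),
    library_size_mean = as.integer(library_size_mean),
    n_module_genes = as.integer(n_module_genes),
    module_latent_sd = as.numeric(module_latent_sd),
    n_pathway_genes = as.integer(n_pathway_genes),
    pathway_module_share = as.numeric(pathway_module_share),
    ppi_n_background_genes = as.integer(ppi_n_background_genes),
    ppi_edge_prob = as.numeric(ppi_edge_prob),
    regulator_direct_targets = as.integer(regulator_direct_targets),
    clinical_n = as.integer(clinical_n),
    hazard_ratio_high_marker = as.numeric(hazard_ratio_high_marker),
    contingency_counts = as.integer(contingency_counts),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!ok) abort(msg, class = "pathtriage_config_error")
  chk(cfg$n_cells_per_group >= 1, "n_cells_per_group must be >= 1")
  chk(cfg$n_genes >= 1, "n_genes must be >= 1")
  chk(cfg$n_de_genes >= 0, "n_de_genes must be >= 0")
  chk(cfg$nb_dispersion > 0, "nb_dispersion must be > 0")
  chk(cfg$library_size_mean > 0, "library_size_mean must be > 0")
  chk(cfg$n_module_genes >= 0, "n_module_genes must be >= 0")
  chk(cfg$module_latent_sd >= 0, "module_latent_sd must be >= 0")
  chk(cfg$n_pathway_genes >= 1, "n_pathway_genes must be >= 1")
  chk(cfg$pathway_module_share >= 0 && cfg$pathway_module_share <= 1,
      "pathway_module_share must lie in [0, 1]")
  chk(cfg$ppi_edge_prob >= 0 && cfg$ppi_edge_prob <= 1,
      "ppi_edge_prob must lie in [0, 1]")
  chk(cfg$n_de_genes + cfg$n_module_genes <= cfg$n_genes,
      "n_de_genes + n_module_genes must not exceed n_genes")
  chk(cfg$n_pathway_genes <= max(cfg$n_de_genes, cfg$n_pathway_genes),
      "n_pathway_genes invalid")
  chk(cfg$regulator_direct_targets <= cfg$n_pathway_genes,
      "regulator_direct_targets must not exceed n_pathway_genes")
  chk(cfg$regulator_direct_targets >= 1,
      "regulator_direct_targets must be >= 1")
  chk(length(cfg$contingency_counts) == 4 && all(cfg$contingency_counts >= 0),
      "contingency_counts must be four non-negative integers")
  chk(cfg$module_latent_sd == 0 || cfg$n_module_genes == 0 ||
        cfg$n_module_genes >= 1, "module settings inconsistent")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cells: %d x 3 groups, genes: %d (%d DE, %d module, %d pathway)\n",
              x$n_cells_per_group, x$n_genes, x$n_de_genes,
              x$n_module_genes, x$n_pathway_genes))
  cat(sprintf("  ppi: %d background nodes, p = %g; clinical n = %d; seed = %d\n",
              x$ppi_n_background_genes, x$ppi_edge_prob, x$clinical_n, x$seed))
  invisible(x)
}

# Independent RNG sub-streams derived from one seed, so regenerating e.g.
# only the clinical table does not disturb the counts. Offsets are arbitrary
# fixed constants kept below .Machine$integer.max.
sim_substream_seed <- function(cfg, stream = c("counts", "sets", "graph", "clinical")) {
  stream <- match.arg(stream)
  offset <- c(counts = 101L, sets = 202L, graph = 303L, clinical = 404L)[[stream]]
  (cfg$seed %% 1000000L) * 1000L + offset
}

# Canonical pathway symbols used for cosmetic naming of planted pathway
# genes (sized to the 14 PI3K-AKT members reported overexpressed in CRC
# epithelium); longer pathways fall back to PATHWAYnn symbols.
pi3k_akt_symbols <- c(
  "COL1A1", "ITGB4", "COL1A2", "HSP90AA1", "COL6A1", "DDIT4", "SPP1",
  "RHEB", "ATF4", "LAMB3", "ITGA3", "EPHA2", "ITGB1", "HSP90AB1"
)
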