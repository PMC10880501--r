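#' Simulate a protein-protein interaction graph with a planted regulator
#'
#' Builds a simple undirected graph emulating a binary interactome: an
#' Erdos-Renyi background over (module genes + pathway genes +
#' `ppi_n_background_genes` decoy nodes) at edge probability
#' `ppi_edge_prob`, plus two planted structures: the pathway members are
#' wired into a ring among themselves (pathway proteins interact with each
#' other in real interactomes), and the planted regulator is connected
#' directly to `regulator_direct_targets` randomly chosen pathway genes.
#' Background decoy nodes reuse non-module, non-pathway gene symbols from
#' the simulated count matrix where available.
#'
#' @param config A [sim_config()].
#' @param truth The `ground_truth` from [sim_counts()].
#' @return An [interaction_graph()].
#' @examples
#' cfg <- sim_config(n_genes = 120, n_cells_per_group = 10,
#'                   n_de_genes = 14, n_module_genes = 20,
#'                   ppi_n_background_genes = 40)
#' sim <- sim_counts(cfg)
#' g <- sim_ppi(cfg, sim$truth)
#' "MDFI" %in% igraph::V(g$graph)$name
#' @export
sim_ppi <- function(config, truth) {
  config <- validate_sim_config(config)
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(sim_substream_seed(config, "graph"))
  nms <- sim_gene_names(config)
  pool <- c(nms$de[!nms$de %in% nms$pathway], nms$background)
  n_bg <- config$ppi_n_background_genes
  bg <- if (length(pool) >= n_bg) pool[seq_len(n_bg)]
  else c(pool, sprintf("BGNODE%04d", seq_len(n_bg - length(pool))))
  nodes <- unique(c(truth$planted_regulator_id, truth$module_gene_ids,
                    truth$pathway_gene_ids, bg))

  g <- igraph::sample_gnp(length(nodes), config$ppi_edge_prob)
  igraph::V(g)$name <- nodes

  pathway <- truth$pathway_gene_ids
  planted <- character(0)
  if (length(pathway) >= 2) {
    ring <- as.vector(rbind(pathway, c(pathway[-1], pathway[1])))
    planted <- c(planted, ring)
  }
  targets <- sample(pathway, config$regulator_direct_targets)
  planted <- c(planted,
               as.vector(rbind(truth$planted_regulator_id, targets)))
  g <- igraph::simplify(igraph::add_edges(g, planted))

  interaction_graph(
    tibble(
      gene_a = igraph::as_data_frame(g, "edges")$from,
      gene_b = igraph::as_data_frame(g, "edges")$to
    ),
    nodes = nodes
  )
}
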