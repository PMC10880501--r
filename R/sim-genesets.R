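#' Simulate a gene-set collection around the planted pathway
#'
#' Emits one set named `PATHWAY_AKT` that equals the planted pathway genes,
#' plus random decoy sets drawn (without replacement within each set) from
#' the simulated gene universe. Decoys can never coincide with the planted
#' set: any accidental duplicate is redrawn.
#'
#' @param config A [sim_config()].
#' @param truth The `ground_truth` from [sim_counts()].
#' @param n_decoys Number of decoy sets.
#' @param decoy_size_range Inclusive size range decoy sets are drawn from.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `universe` (the simulated gene names).
#' @examples
#' cfg <- sim_config(n_genes = 120, n_cells_per_group = 10,
#'                   n_de_genes = 14, n_module_genes = 20)
#' sim <- sim_counts(cfg)
#' gs <- sim_gene_sets(cfg, sim$truth)
#' length(gs$sets[["PATHWAY_AKT"]])
#' @export
sim_gene_sets <- function(config, truth, n_decoys = 20,
                          decoy_size_range = c(10, 30)) {
  config <- validate_sim_config(config)
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(sim_substream_seed(config, "sets"))
  universe <- sim_gene_names(config)$genes
  pathway <- truth$pathway_gene_ids
  sets <- list(PATHWAY_AKT = pathway)
  sizes <- sample(seq(decoy_size_range[1], decoy_size_range[2]),
                  n_decoys, replace = TRUE)
  for (i in seq_len(n_decoys)) {
    repeat {
      s <- sort(sample(universe, min(sizes[i], length(universe))))
      if (!setequal(s, pathway)) break
    }
    sets[[sprintf("DECOY_%02d", i)]] <- s
  }
  gene_set_collection(sets, universe = universe)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors; members are de-duplicated.
#' @param universe Optional character vector restricting the gene universe.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    abort("sets must have unique names", class = "pathtriage_input_error")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (sizes %d-%d)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}
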