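#' Level-1/2/3 target counts from one candidate gene
#'
#' Breadth-first shortest-path distances from the source gene classify each
#' pathway target by its interaction level: level 1 = direct partner,
#' level 2 = one intermediate, level 3 = two intermediates. Each target is
#' counted once, at its shortest level, so the level counts partition the
#' reachable targets. The source's own membership in the target set is
#' ignored.
#'
#' @param g An [interaction_graph()].
#' @param source Candidate gene symbol (must be a node).
#' @param targets Character vector of pathway gene symbols.
#' @param max_level Deepest level counted.
#' @return Tibble with one row: `gene`, `level1`..`level3` (or up to
#'   `max_level`), `total`.
#' @examples
#' g <- interaction_graph(tibble::tibble(gene_a = c("A", "C"),
#'                                       gene_b = c("C", "B")))
#' shortest_levels(g, "A", "B")
#' @export
shortest_levels <- function(g, source, targets, max_level = 3) {
  stopifnot(inherits(g, "interaction_graph"))
  nodes <- igraph::V(g$graph)$name
  if (!source %in% nodes)
    abort(sprintf("source '%s' not in graph", source),
          class = "pathtriage_input_error")
  if (length(targets) == 0)
    abort("targets must be non-empty", class = "pathtriage_input_error")
  targets <- setdiff(unique(targets), source)
  present <- intersect(targets, nodes)
  if (length(present) == 0)
    warn("no target gene is present in the graph; all level counts are 0")
  counts <- rep(0L, max_level)
  if (length(present) > 0) {
    d <- igraph::distances(g$graph, v = source, to = present,
                           algorithm = "unweighted")[1, ]
    for (k in seq_len(max_level)) counts[k] <- sum(d == k)
  }
  out <- tibble(gene = source)
  for (k in seq_len(max_level)) out[[paste0("level", k)]] <- counts[k]
  out$total <- sum(counts)
  out
}

#' Rank candidate genes by their pathway level counts
#'
#' Computes [shortest_levels()] for every candidate and sorts descending by
#' the level-count sum; ties break by (level1, level2, level3) descending,
#' then gene symbol ascending. Candidates absent from the graph score all
#' zeros. Duplicate candidates are dropped with a warning.
#'
#' @param g An [interaction_graph()].
#' @param candidates Character vector of candidate gene symbols.
#' @param targets Character vector of pathway gene symbols.
#' @param max_level Deepest level counted.
#' @return Tibble with `gene`, `level1`..`levelk`, `total`, `rank`.
#' @export
rank_candidates <- function(g, candidates, targets, max_level = 3) {
  stopifnot(inherits(g, "interaction_graph"))
  if (length(candidates) == 0)
    abort("candidates must be non-empty", class = "pathtriage_input_error")
  if (anyDuplicated(candidates)) {
    warn("duplicate candidate symbols removed")
    candidates <- unique(candidates)
  }
  nodes <- igraph::V(g$graph)$name
  lvl_cols <- paste0("level", seq_len(max_level))
  rows <- purrr::map_dfr(candidates, function(cand) {
    if (!cand %in% nodes) {
      out <- tibble(gene = cand)
      for (cl in lvl_cols) out[[cl]] <- 0L
      out$total <- 0L
      out
    } else {
      suppressWarnings(shortest_levels(g, cand, targets, max_level))
    }
  })
  ord <- do.call(order, c(
    list(-rows$total),
    lapply(lvl_cols, function(cl) -rows[[cl]]),
    list(rows$gene)
  ))
  rows <- rows[ord, ]
  rows$rank <- seq_len(nrow(rows))
  rows
}

#' Direct interaction partners of a gene
#'
#' The sorted level-1 neighbourhood, for reporting a candidate's contact
#' map.
#'
#' @param g An [interaction_graph()].
#' @param gene Gene symbol (must be a node).
#' @return Sorted character vector of neighbours (empty for isolated nodes).
#' @export
direct_partners <- function(g, gene) {
  stopifnot(inherits(g, "interaction_graph"))
  if (!gene %in% igraph::V(g$graph)$name)
    abort(sprintf("gene '%s' not in graph", gene),
          class = "pathtriage_input_error")
  sort(igraph::neighbors(g$graph, gene)$name)
}
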