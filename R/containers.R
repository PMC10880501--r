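#' Construct a gene-by-cell count matrix container
#'
#' The raw input of the pipeline: non-negative integer counts with per-cell
#' annotations. Group labels come from `cell_meta$group` and are used directly
#' for differential expression (no clustering is performed by this package).
#'
#' @param counts Integer matrix, genes in rows, cells in columns, with
#'   rownames (gene symbols) and colnames (cell barcodes).
#' @param cell_meta Data frame with one row per cell: columns `cell`,
#'   `sample`, `group` (values among tumor/normal/border) and optionally
#'   further per-cell covariates.
#' @return A `count_matrix` object.
#' @examples
#' m <- count_matrix(
#'   matrix(0:3, 2, 2, dimnames = list(c("A", "B"), c("c1", "c2"))),
#'   tibble::tibble(cell = c("c1", "c2"), sample = "s1",
#'                  group = c("tumor", "normal"))
#' )
#' dim(m$counts)
#' @export
count_matrix <- function(counts, cell_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    abort("counts must carry gene rownames and cell colnames",
          class = "pathtriage_input_error")
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    abort("gene and cell identifiers must be unique",
          class = "pathtriage_input_error")
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers",
          class = "pathtriage_input_error")
  cell_meta <- as_tibble(cell_meta)
  if (!all(c("cell", "group") %in% names(cell_meta)))
    abort("cell_meta needs at least 'cell' and 'group' columns",
          class = "pathtriage_input_error")
  if (!setequal(cell_meta$cell, colnames(counts)) ||
      nrow(cell_meta) != ncol(counts))
    abort("cell_meta must label every cell exactly once",
          class = "pathtriage_input_error")
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell), ]
  structure(
    list(counts = counts, genes = rownames(counts),
         cells = colnames(counts) %||% character(0), cell_meta = cell_meta),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  print(dplyr::count(x$cell_meta, .data$group))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

new_normalized_matrix <- function(values, scale_factor, source_dim) {
  structure(
    list(values = values, scale_factor = scale_factor, source_dim = source_dim),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d genes x %d cells (scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' Construct an undirected interaction graph from an edge table
#'
#' Self-loops and duplicate (unordered) edges are dropped so the graph is
#' simple. Isolated nodes can be declared through `nodes`.
#'
#' @param edges Data frame with character columns `gene_a` and `gene_b`.
#' @param nodes Optional character vector of node names to include even when
#'   isolated.
#' @return An `interaction_graph` object wrapping an igraph graph.
#' @examples
#' g <- interaction_graph(tibble::tibble(gene_a = "A", gene_b = "B"))
#' igraph::vcount(g$graph)
#' @export
interaction_graph <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("gene_a", "gene_b") %in% names(edges)))
    abort("edges needs 'gene_a' and 'gene_b' columns",
          class = "pathtriage_input_error")
  edges <- dplyr::filter(edges, .data$gene_a != .data$gene_b)
  all_nodes <- unique(c(edges$gene_a, edges$gene_b, nodes))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")],
    directed = FALSE, vertices = all_nodes
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Edge table of an interaction graph
#'
#' @param g An `interaction_graph`.
#' @return Tibble with columns `gene_a`, `gene_b`, one row per undirected edge.
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  e <- igraph::as_data_frame(g$graph, what = "edges")
  tibble(gene_a = e$from, gene_b = e$to)
}
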