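#' Write and read a count matrix
#'
#' Two on-disk layouts are supported: `"mtx"` (MatrixMarket triplet plus
#' `genes.tsv` and `barcodes.tsv`, with cell annotations as extra columns of
#' the barcode file) and `"tsv"` (dense gene x cell table with a `gene`
#' column, annotations in a sidecar `<prefix>_cells.tsv`).
#'
#' @param m A [count_matrix()].
#' @param path For `"mtx"` a directory; for `"tsv"` a file path prefix.
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "count_matrix"))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble(gene = m$genes),
                     file.path(path, "genes.tsv"), col_names = FALSE)
    readr::write_tsv(m$cell_meta, file.path(path, "barcodes.tsv"))
  } else {
    df <- as.data.frame(m$counts)
    df <- cbind(gene = m$genes, df)
    readr::write_tsv(df, paste0(path, "_counts.tsv"))
    readr::write_tsv(m$cell_meta, paste0(path, "_cells.tsv"))
  }
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    counts <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
    genes <- readr::read_tsv(file.path(path, "genes.tsv"),
                             col_names = "gene", show_col_types = FALSE)$gene
    meta <- readr::read_tsv(file.path(path, "barcodes.tsv"),
                            show_col_types = FALSE)
    dimnames(counts) <- list(genes, meta$cell)
  } else {
    df <- readr::read_tsv(paste0(path, "_counts.tsv"), show_col_types = FALSE)
    genes <- df$gene
    counts <- as.matrix(df[, -1])
    rownames(counts) <- genes
    meta <- readr::read_tsv(paste0(path, "_cells.tsv"), show_col_types = FALSE)
  }
  count_matrix(counts, meta)
}

#' Write and read GMT gene-set files
#'
#' Standard tab-separated GMT: set name, description, then members.
#'
#' @param collection A [gene_set_collection()].
#' @param path File path.
#' @return `path` invisibly for the writer; a [gene_set_collection()] for
#'   the reader.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "synthetic", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  gene_set_collection(sets)
}

#' Write and read interaction edge lists
#'
#' Two-column tab-separated file with header `gene_a` / `gene_b`.
#'
#' @param g An [interaction_graph()].
#' @param path File path.
#' @param columns For the reader: names of the two symbol columns to use
#'   (tolerates wider PSI-MITAB-like tables).
#' @return `path` invisibly for the writer; an [interaction_graph()] for
#'   the reader.
#' @export
write_edges <- function(g, path) {
  readr::write_tsv(graph_edges(g), path)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path, columns = c("gene_a", "gene_b")) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(columns %in% names(df)))
    abort(sprintf("edge file lacks columns %s", paste(columns, collapse = ", ")),
          class = "pathtriage_input_error")
  interaction_graph(tibble(gene_a = as.character(df[[columns[1]]]),
                           gene_b = as.character(df[[columns[2]]])))
}

#' Write and read a clinical table as CSV
#'
#' @param ct A clinical table tibble.
#' @param path File path.
#' @param column_map Optional named character vector mapping this package's
#'   column names to the file's column names (reader only).
#' @return `path` invisibly for the writer; a clinical tibble for the
#'   reader.
#' @export
write_clinical <- function(ct, path) {
  readr::write_csv(ct, path)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path, column_map = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      df[[nm]] <- df[[column_map[[nm]]]]
    }
  }
  as_tibble(df)
}

#' Write ground truth as JSON
#'
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(
      de_gene_ids = truth$de_gene_ids,
      module_gene_ids = truth$module_gene_ids,
      pathway_gene_ids = truth$pathway_gene_ids,
      planted_regulator_id = truth$planted_regulator_id,
      latent_factor = as.list(truth$latent_factor)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
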