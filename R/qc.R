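#' Per-cell quality-control metrics
#'
#' Computes the standard QC triplet for each cell: `n_count` (total UMI),
#' `n_feature` (genes detected with count > 0) and `percent_mt` (percentage
#' of counts on genes whose symbol starts with `mito_prefix`). A cell with
#' zero counts has `percent_mt` defined as 0.
#'
#' @param m A [count_matrix()].
#' @param mito_prefix Symbol prefix identifying mitochondrial genes.
#' @return Tibble with columns `cell`, `group`, `n_count`, `n_feature`,
#'   `percent_mt`.
#' @examples
#' m <- count_matrix(
#'   matrix(c(2, 3, 0), 3, 1, dimnames = list(c("A", "MT-B", "C"), "c1")),
#'   tibble::tibble(cell = "c1", sample = "s", group = "tumor")
#' )
#' compute_qc(m)
#' @export
compute_qc <- function(m, mito_prefix = "MT-") {
  stopifnot(inherits(m, "count_matrix"))
  if (nrow(m$counts) == 0 || ncol(m$counts) == 0)
    abort("empty count matrix", class = "pathtriage_input_error")
  n_count <- colSums(m$counts)
  n_feature <- colSums(m$counts > 0)
  is_mt <- startsWith(m$genes, mito_prefix)
  mt_count <- if (any(is_mt)) colSums(m$counts[is_mt, , drop = FALSE]) else 0
  percent_mt <- ifelse(n_count > 0, 100 * mt_count / n_count, 0)
  tibble(
    cell = m$cells,
    group = m$cell_meta$group,
    n_count = as.numeric(n_count),
    n_feature = as.integer(n_feature),
    percent_mt = as.numeric(percent_mt)
  )
}

#' Filter cells on the mitochondrial-fraction threshold
#'
#' Retains exactly the cells with `percent_mt` strictly below
#' `max_percent_mt` ("below 20%" semantics), preserving cell order. An
#' optional minimum detected-gene floor removes empty/degenerate cells.
#'
#' @param m A [count_matrix()].
#' @param qc QC tibble from [compute_qc()] for `m`; computed on the fly when
#'   omitted.
#' @param max_percent_mt Strict upper bound on `percent_mt` (percent).
#' @param min_n_feature Minimum detected genes per cell (0 disables).
#' @return A filtered [count_matrix()].
#' @export
filter_cells <- function(m, qc = compute_qc(m), max_percent_mt = 20,
                         min_n_feature = 0) {
  stopifnot(inherits(m, "count_matrix"))
  qc <- qc[match(m$cells, qc$cell), ]
  keep <- qc$percent_mt < max_percent_mt & qc$n_feature >= min_n_feature
  if (!any(keep)) {
    warn("all cells removed by QC filter")
  }
  count_matrix(m$counts[, keep, drop = FALSE],
               m$cell_meta[keep, , drop = FALSE])
}

#' Log-normalize counts
#'
#' `value(g, c) = ln(1 + count(g, c) * scale_factor / n_count(c))`; cells
#' with zero total count stay all-zero.
#'
#' @param m A [count_matrix()].
#' @param scale_factor Target library size before the log1p transform.
#' @return A `normalized_matrix` (gene x cell real values).
#' @examples
#' m <- count_matrix(
#'   matrix(1, 1, 1, dimnames = list("A", "c1")),
#'   tibble::tibble(cell = "c1", sample = "s", group = "tumor")
#' )
#' normalize_counts(m)$values  # ln(10001)
#' @export
normalize_counts <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  n_count <- colSums(m$counts)
  f <- ifelse(n_count > 0, scale_factor / n_count, 0)
  values <- log1p(sweep(m$counts, 2, f, "*"))
  new_normalized_matrix(values, scale_factor, dim(m$counts))
}

#' Scale genes and embed cells with PCA
#'
#' Per-gene standardisation (mean 0, variance 1; zero-variance genes are
#' dropped), clipping of standardised values at `+/- clip`, then the top
#' `n_components` principal components of the cells. The SVD sign is fixed
#' so that each component's largest-magnitude gene loading is positive,
#' making the embedding reproducible bit-for-bit.
#'
#' @param nm A `normalized_matrix` from [normalize_counts()].
#' @param n_components Number of components to keep (truncated with a
#'   warning when it exceeds what the matrix supports).
#' @param clip Symmetric clipping bound applied after scaling.
#' @return List with `embedding` (cell x component matrix, columns `PC1`...),
#'   `sdev` (component standard deviations), `loadings` (gene x component),
#'   and `scaled` (the clipped gene x cell matrix used).
#' @export
scale_and_pca <- function(nm, n_components = 30, clip = 10) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- nm$values
  if (ncol(x) < 2)
    abort("need at least 2 cells for PCA", class = "pathtriage_input_error")
  v <- apply(x, 1, var)
  x <- x[v > 0, , drop = FALSE]
  x <- t(scale(t(x)))
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  max_comp <- min(nrow(x), ncol(x) - 1L)
  if (n_components > max_comp) {
    warn(sprintf("n_components truncated from %d to %d", n_components, max_comp))
    n_components <- max_comp
  }
  # PCA over cells: center each gene (already centred), SVD of gene x cell
  sv <- svd(x, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    u <- sv$u[, j]
    sign(u[which.max(abs(u))])
  }, numeric(1))
  flip[flip == 0] <- 1
  u <- sweep(sv$u[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  vmat <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  d <- sv$d[seq_len(n_components)]
  emb <- sweep(vmat, 2, d, "*")
  dimnames(emb) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  dimnames(u) <- list(rownames(x), paste0("PC", seq_len(n_components)))
  list(
    embedding = emb,
    sdev = d / sqrt(max(ncol(x) - 1, 1)),
    loadings = u,
    scaled = x
  )
}
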