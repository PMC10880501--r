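#' Detection fraction of a gene within a cell group
#'
#' Fraction of cells in the group with expression strictly greater than 0.
#'
#' @param values Numeric vector of per-cell expression for one gene.
#' @param mask Logical vector selecting the group's cells.
#' @return A fraction in `[0, 1]`.
#' @examples
#' detection_fraction(c(0, 1.2, 0, 3), c(TRUE, TRUE, TRUE, TRUE))
#' @export
detection_fraction <- function(values, mask) {
  if (!any(mask)) abort("empty group", class = "pathtriage_input_error")
  mean(values[mask] > 0)
}

#' Average log fold change between two groups
#'
#' Computed on log-normalized values with back-transformation:
#' `ln(mean(expm1(x1)) + pseudocount) - ln(mean(expm1(x2)) + pseudocount)`
#' (natural-log units, pre-v4 Seurat-era convention).
#'
#' @param values Numeric vector of per-cell log-normalized expression.
#' @param mask_1,mask_2 Logical masks for the two groups.
#' @param pseudocount Pseudo-count added to back-transformed means.
#' @return Natural-log fold change (group 1 minus group 2).
#' @export
avg_logfc <- function(values, mask_1, mask_2, pseudocount = 1) {
  if (!any(mask_1) || !any(mask_2))
    abort("both groups must be non-empty", class = "pathtriage_input_error")
  log(mean(expm1(values[mask_1])) + pseudocount) -
    log(mean(expm1(values[mask_2])) + pseudocount)
}

# Two-sided Wilcoxon rank-sum p-values for every row of `x`. Tie-free rows
# of small samples (n <= 30) use the exact rank-sum distribution; all other
# rows use the normal approximation with tie correction (no continuity
# correction), which is the regime differential expression actually runs in.
wilcoxon_p_rows <- function(x, mask_1, mask_2) {
  idx <- c(which(mask_1), which(mask_2))
  n1 <- sum(mask_1); n2 <- sum(mask_2); n <- n1 + n2
  apply(x[, idx, drop = FALSE], 1, function(v) {
    r <- rank(v)
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    has_ties <- anyDuplicated(v) > 0
    if (!has_ties && n <= 30) {
      p <- if (w > n1 * n2 / 2)
        stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE)
      else stats::pwilcox(w, n1, n2)
      return(min(1, 2 * p))
    }
    ties <- table(v)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (w - n1 * n2 / 2) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  })
}

#' Two-group Wilcoxon differential expression
#'
#' Per-gene tumor-versus-normal style differential expression on a
#' log-normalized matrix. Genes enter the test when
#' `max(pct_1, pct_2) > min_pct` and `|avg_logFC| > min_abs_logfc`;
#' passing genes get a two-sided Wilcoxon rank-sum p (normal approximation
#' with tie correction) and a Bonferroni adjustment over the number of
#' genes actually tested. Output rows are sorted by `p_val`, ties broken by
#' gene symbol.
#'
#' @param nm A `normalized_matrix` from [normalize_counts()].
#' @param labels Character vector of per-cell group labels (matching the
#'   matrix columns).
#' @param group_1,group_2 Labels of the two groups to compare (group 1 is
#'   the "tumor" side: positive `avg_logFC` means higher there).
#' @param min_pct Detection-fraction screen (strictly exceeded in at least
#'   one group).
#' @param min_abs_logfc Absolute log-fold-change screen (strictly exceeded).
#' @param pseudocount Passed to [avg_logfc()].
#' @return Tibble with columns `gene`, `p_val`, `p_val_adj`, `avg_logFC`,
#'   `pct_1`, `pct_2` (detection fractions, reported as fractions in
#'   `[0, 1]`), one row per screened-in gene.
#' @examples
#' sim <- sim_counts(sim_config(n_genes = 150, n_cells_per_group = 40,
#'                              n_de_genes = 14, n_module_genes = 20))
#' nm <- normalize_counts(sim$counts)
#' de <- wilcoxon_de(nm, sim$counts$cell_meta$group, "tumor", "normal")
#' head(de, 3)
#' @export
wilcoxon_de <- function(nm, labels, group_1 = "tumor", group_2 = "normal",
                        min_pct = 0.25, min_abs_logfc = 0.25,
                        pseudocount = 1) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- nm$values
  if (length(labels) != ncol(x))
    abort("labels must match the matrix columns", class = "pathtriage_input_error")
  mask_1 <- labels == group_1
  mask_2 <- labels == group_2
  if (sum(mask_1) < 2 || sum(mask_2) < 2)
    abort("both groups need at least 2 cells", class = "pathtriage_input_error")

  pct_1 <- rowMeans(x[, mask_1, drop = FALSE] > 0)
  pct_2 <- rowMeans(x[, mask_2, drop = FALSE] > 0)
  lfc <- log(rowMeans(expm1(x[, mask_1, drop = FALSE])) + pseudocount) -
    log(rowMeans(expm1(x[, mask_2, drop = FALSE])) + pseudocount)

  pass <- pmax(pct_1, pct_2) > min_pct & abs(lfc) > min_abs_logfc
  n_tested <- sum(pass)
  if (n_tested == 0) {
    return(tibble(gene = character(), p_val = numeric(),
                  p_val_adj = numeric(), avg_logFC = numeric(),
                  pct_1 = numeric(), pct_2 = numeric()))
  }
  p <- wilcoxon_p_rows(x[pass, , drop = FALSE], mask_1, mask_2)
  out <- tibble(
    gene = rownames(x)[pass],
    p_val = as.numeric(p),
    p_val_adj = pmin(1, p * n_tested),
    avg_logFC = lfc[pass],
    pct_1 = pct_1[pass],
    pct_2 = pct_2[pass]
  )
  dplyr::arrange(out, .data$p_val, .data$gene)
}
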