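#' Select the most variable genes
#'
#' Ranks genes by variance across cells on the normalized values; ties are
#' broken by gene symbol so the selection is reproducible.
#'
#' @param nm A `normalized_matrix`.
#' @param n Number of genes to keep (all genes, with a warning, when `n`
#'   exceeds the gene count).
#' @return Character vector of selected gene symbols (variance order).
#' @export
select_variable_genes <- function(nm, n = 5000) {
  stopifnot(inherits(nm, "normalized_matrix"))
  v <- apply(nm$values, 1, var)
  if (n > length(v)) {
    warn(sprintf("n = %d exceeds gene count %d; keeping all genes",
                 n, length(v)))
    n <- length(v)
  }
  ord <- order(-v, rownames(nm$values))
  rownames(nm$values)[ord][seq_len(n)]
}

#' Soft-threshold scan by scale-free topology fit
#'
#' For each candidate power, the network connectivity
#' `k_m = sum_{n != m} |S_mn|^power` is computed, binned into `n_bins`
#' equal-width intervals, and the log10 bin frequency is regressed on the
#' log10 mean bin connectivity. The signed fit index is
#' `R^2 * sign(-slope)`, so only declining (scale-free-like) degree
#' distributions score highly. The chosen power is the smallest one whose
#' signed fit reaches `target_r2`; when none does, the power maximizing the
#' signed fit is returned with a warning.
#'
#' @param S Gene-gene Pearson correlation matrix.
#' @param powers Candidate integer powers.
#' @param target_r2 Scale-free fit threshold (0.85 is the conventional
#'   criterion).
#' @param n_bins Number of equal-width connectivity bins for the fit.
#' @return List with `beta` (chosen power) and `profile`, a tibble with
#'   columns `power`, `r_squared` (signed), `slope`, `mean_k`.
#' @export
soft_threshold_scan <- function(S, powers = 1:20, target_r2 = 0.85,
                                n_bins = 10) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  absS <- abs(S)
  profile <- purrr::map_dfr(powers, function(p) {
    k <- colSums(absS^p) - 1
    fit <- scale_free_fit(k, n_bins)
    tibble(power = p, r_squared = fit$r_squared, slope = fit$slope,
           mean_k = mean(k))
  })
  ok <- which(profile$r_squared >= target_r2)
  if (length(ok) > 0) {
    beta <- profile$power[min(ok)]
  } else {
    warn(sprintf(
      "no power reached signed R^2 >= %.2f; using the best (R^2 = %.3f)",
      target_r2, max(profile$r_squared, na.rm = TRUE)))
    beta <- profile$power[which.max(profile$r_squared)]
  }
  list(beta = beta, profile = profile)
}

# Signed scale-free fit index of a connectivity vector: equal-width binning
# of k, least squares of log10(frequency) on log10(mean k), R^2 signed by
# the negated slope. Degenerate inputs (all-equal k, < 3 usable bins)
# return r_squared 0.
scale_free_fit <- function(k, n_bins = 10) {
  if (length(unique(k)) < 2 || diff(range(k)) == 0)
    return(list(r_squared = 0, slope = NA_real_))
  b <- cut(k, breaks = n_bins, include.lowest = TRUE)
  dk <- tapply(k, b, mean)
  freq <- as.vector(table(b)) / length(k)
  ok <- !is.na(dk) & dk > 0 & freq > 0
  if (sum(ok) < 3) return(list(r_squared = 0, slope = NA_real_))
  fit <- lm(log10(freq[ok]) ~ log10(dk[ok]))
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r_squared = r2 * -sign(slope), slope = slope)
}

#' Soft-threshold adjacency
#'
#' `A_mn = |S_mn|^beta` (unsigned weighted network).
#'
#' @param S Correlation matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return Adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(S, beta) {
  stopifnot(beta >= 1)
  abs(S)^beta
}

#' Topological overlap matrix
#'
#' Unsigned TOM:
#' `TOM_mn = (l_mn + A_mn) / (min(k_m, k_n) + 1 - A_mn)` with
#' `l_mn = sum_{u != m,n} A_mu A_un` and `k_m = sum_{u != m} A_mu`;
#' the diagonal is 1.
#'
#' @param A Symmetric adjacency matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @return TOM matrix (symmetric, entries in `[0, 1]`, unit diagonal).
#' @export
tom_similarity <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  diag(A) <- 1
  k <- colSums(A) - 1
  # (A %*% A)_mn = sum_u A_mu A_un includes u = m and u = n, each
  # contributing A_mn (diag(A) = 1); remove both.
  l <- A %*% A - 2 * A
  tom <- (l + A) / (outer(k, k, pmin) + 1 - A)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect modules by average-linkage clustering of TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, a static tree cut
#' at `cut_height`, and merging of clusters smaller than `min_module_size`
#' into the unassigned "grey" label. Surviving modules are labelled "M1",
#' "M2", ... in decreasing size order (ties broken by first gene symbol).
#'
#' @param diss_tom Square symmetric dissimilarity matrix (`1 - TOM`).
#' @param min_module_size Smallest cluster kept as a module.
#' @param cut_height Static cut height on the dendrogram.
#' @return Tibble with columns `gene`, `module`.
#' @export
cluster_modules <- function(diss_tom, min_module_size = 30, cut_height = 0.99) {
  stopifnot(is.matrix(diss_tom), nrow(diss_tom) == ncol(diss_tom))
  genes <- rownames(diss_tom) %||% sprintf("g%d", seq_len(nrow(diss_tom)))
  hc <- hclust(as.dist(diss_tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  tab <- table(raw)
  keep <- names(tab)[tab >= min_module_size]
  module <- rep("grey", length(raw))
  if (length(keep) > 0) {
    keep_df <- tibble(
      cluster = keep,
      size = as.integer(tab[keep]),
      first_gene = vapply(keep, function(cl) min(genes[raw == cl]), character(1))
    )
    keep_df <- dplyr::arrange(keep_df, dplyr::desc(.data$size), .data$first_gene)
    label <- setNames(paste0("M", seq_len(nrow(keep_df))), keep_df$cluster)
    in_keep <- as.character(raw) %in% keep
    module[in_keep] <- label[as.character(raw)[in_keep]]
  }
  tibble(gene = genes, module = module)
}

#' Module eigengenes
#'
#' The eigengene of a module is the unit-norm first principal component of
#' the module's per-gene standardized expression across cells, with its
#' sign aligned to the module's average expression profile.
#'
#' @param nm A `normalized_matrix`.
#' @param assignment Tibble from [cluster_modules()].
#' @return Tibble with one row per cell: `cell` plus one column per
#'   non-grey module.
#' @export
module_eigengenes <- function(nm, assignment) {
  stopifnot(inherits(nm, "normalized_matrix"))
  mods <- sort(setdiff(unique(assignment$module), "grey"))
  cells <- colnames(nm$values)
  out <- tibble(cell = cells)
  for (m in mods) {
    genes <- assignment$gene[assignment$module == m]
    x <- nm$values[genes, , drop = FALSE]
    v <- apply(x, 1, var)
    x <- x[v > 0, , drop = FALSE]
    x <- t(scale(t(x)))
    sv <- svd(x, nu = 0, nv = 1)
    eg <- sv$v[, 1]
    avg <- colMeans(x)
    if (cor(eg, avg) < 0) eg <- -eg
    out[[m]] <- eg / sqrt(sum(eg^2))
  }
  out
}

#' Correlate module eigengenes with pathway genes and traits
#'
#' Pearson correlation (with two-sided t-test p-values) of each module
#' eigengene against (a) the expression of each pathway gene present in the
#' matrix and (b) each numeric per-cell trait. The best module is the one
#' with the greatest number of pathway genes correlated at
#' `|r| > r_threshold` and `p < p_threshold`; ties are broken by mean
#' `|r|` over pathway genes.
#'
#' @param nm A `normalized_matrix`.
#' @param assignment Tibble from [cluster_modules()].
#' @param pathway_genes Character vector of pathway gene symbols.
#' @param traits Optional data frame of numeric per-cell traits (same cell
#'   order as the matrix columns). Constant traits are reported with `NA`
#'   correlation.
#' @param r_threshold,p_threshold Pathway-gene correlation cutoffs used to
#'   score modules.
#' @return List with `correlations` (tibble: `module`, `variable`, `type`,
#'   `r`, `p`) and `best_module` (label or `NA` when no module exists).
#' @export
module_pathway_correlation <- function(nm, assignment, pathway_genes,
                                       traits = NULL, r_threshold = 0.3,
                                       p_threshold = 0.05) {
  stopifnot(inherits(nm, "normalized_matrix"))
  eg <- module_eigengenes(nm, assignment)
  mods <- setdiff(names(eg), "cell")
  if (length(mods) == 0)
    return(list(correlations = tibble(module = character(), variable = character(),
                                      type = character(), r = numeric(),
                                      p = numeric()),
                best_module = NA_character_))
  present <- intersect(pathway_genes, rownames(nm$values))
  missing <- setdiff(pathway_genes, present)
  if (length(missing) > 0)
    warn(sprintf("%d pathway genes absent from the matrix; skipped",
                 length(missing)))
  vars <- list()
  for (g in present) vars[[g]] <- list(x = nm$values[g, ], type = "pathway_gene")
  if (!is.null(traits)) {
    traits <- as_tibble(traits)
    for (tr in names(traits)) {
      if (is.numeric(traits[[tr]]))
        vars[[tr]] <- list(x = traits[[tr]], type = "trait")
    }
  }
  n <- nrow(eg)
  rows <- purrr::map_dfr(mods, function(m) {
    purrr::imap_dfr(vars, function(v, nmv) {
      if (sd(v$x) == 0 || sd(eg[[m]]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- cor(eg[[m]], v$x)
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * pt(-abs(tstat), n - 2)
      }
      tibble(module = m, variable = nmv, type = v$type, r = r, p = p)
    })
  })
  path_rows <- dplyr::filter(rows, .data$type == "pathway_gene", !is.na(.data$r))
  score <- dplyr::summarise(
    dplyr::group_by(path_rows, .data$module),
    n_hits = sum(abs(.data$r) > r_threshold & .data$p < p_threshold),
    mean_abs_r = mean(abs(.data$r)),
    .groups = "drop"
  )
  score <- dplyr::arrange(score, dplyr::desc(.data$n_hits),
                          dplyr::desc(.data$mean_abs_r), .data$module)
  best <- if (nrow(score) > 0) score$module[1] else mods[1]
  list(correlations = rows, best_module = best)
}

#' Build the full weighted co-expression network
#'
#' Convenience wrapper chaining gene selection, correlation, the
#' soft-threshold scan, adjacency, and TOM.
#'
#' @param nm A `normalized_matrix`.
#' @param n_genes Number of top-variance genes to keep.
#' @param powers,target_r2,n_bins Passed to [soft_threshold_scan()].
#' @return A `coexpr_network` list: `genes`, `S`, `beta`, `profile`, `A`,
#'   `tom`.
#' @export
coexpr_network <- function(nm, n_genes = 5000, powers = 1:20,
                           target_r2 = 0.85, n_bins = 10) {
  genes <- select_variable_genes(nm, n_genes)
  keep <- apply(nm$values[genes, , drop = FALSE], 1, var) > 0
  genes <- genes[keep]  # constant genes have no defined correlation
  S <- cor(t(nm$values[genes, , drop = FALSE]))
  scan <- soft_threshold_scan(S, powers, target_r2, n_bins)
  A <- adjacency_matrix(S, scan$beta)
  structure(
    list(genes = genes, S = S, beta = scan$beta, profile = scan$profile,
         A = A, tom = tom_similarity(A)),
    class = "coexpr_network"
  )
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("<coexpr_network> %d genes, beta = %d (signed R^2 = %.3f)\n",
              length(x$genes), x$beta,
              x$profile$r_squared[x$profile$power == x$beta]))
  invisible(x)
}
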