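#' Tidiers for pathtriage result objects
#'
#' Broom-style methods: `tidy()` returns the per-item table of a result,
#' `glance()` a one-row model summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name pathtriage-tidiers
NULL

#' @rdname pathtriage-tidiers
#' @exportS3Method generics::tidy
tidy.triage_report <- function(x, ...) {
  x$ranking
}

#' @rdname pathtriage-tidiers
#' @exportS3Method generics::glance
glance.triage_report <- function(x, ...) {
  tibble(
    top_gene = x$top_gene,
    best_module = x$best_module,
    beta = x$network$beta,
    n_cells = x$provenance$n_cells_kept,
    n_de_tested = nrow(x$de),
    n_de_significant = sum(x$de$p_val_adj < 0.05),
    top_set = x$top_set,
    os_logrank_p = x$clinical$os$test$p,
    chi_square = x$clinical$chisq$chi_square,
    auc = x$clinical$roc$auc
  )
}

#' @rdname pathtriage-tidiers
#' @exportS3Method generics::tidy
tidy.coexpr_network <- function(x, ...) {
  x$profile
}

#' @rdname pathtriage-tidiers
#' @exportS3Method generics::glance
glance.coexpr_network <- function(x, ...) {
  tibble(
    n_genes = length(x$genes),
    beta = x$beta,
    r_squared = x$profile$r_squared[x$profile$power == x$beta],
    mean_k = x$profile$mean_k[x$profile$power == x$beta]
  )
}

#' @rdname pathtriage-tidiers
#' @exportS3Method generics::tidy
tidy.km_result <- function(x, ...) {
  x$curves
}

#' @rdname pathtriage-tidiers
#' @exportS3Method generics::glance
glance.km_result <- function(x, ...) {
  x$test
}
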