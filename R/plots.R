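#' QC metric violins
#'
#' @param qc QC tibble from [compute_qc()].
#' @return A ggplot object.
#' @export
plot_qc <- function(qc) {
  long <- tidyr::pivot_longer(qc, c("n_count", "n_feature", "percent_mt"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Volcano plot of differential expression
#'
#' @param de Tibble from [wilcoxon_de()].
#' @param p_cut,lfc_cut Highlight thresholds.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, p_cut = 0.05, lfc_cut = 0.25) {
  de <- dplyr::mutate(
    de,
    significant = .data$p_val_adj < p_cut & abs(.data$avg_logFC) > lfc_cut
  )
  ggplot2::ggplot(de, ggplot2::aes(x = .data$avg_logFC,
                                   y = -log10(pmax(.data$p_val, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::theme_bw() +
    ggplot2::labs(x = "avg logFC (natural log)", y = "-log10 p")
}

#' Scale-free fit profile across candidate powers
#'
#' @param profile Tibble from [soft_threshold_scan()] (`$profile`).
#' @param target_r2 Reference line.
#' @return A ggplot object.
#' @export
plot_scale_free <- function(profile, target_r2 = 0.85) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$power, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = target_r2, linetype = 2, colour = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::theme_bw() +
    ggplot2::labs(x = "soft threshold power", y = "signed scale-free R^2")
}

#' Module-pathway/trait correlation heatmap
#'
#' @param correlations Tibble from [module_pathway_correlation()].
#' @return A ggplot object.
#' @export
plot_module_correlation <- function(correlations) {
  ggplot2::ggplot(correlations,
                  ggplot2::aes(x = .data$variable, y = .data$module,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}

#' Kaplan-Meier curves for a marker median split
#'
#' @param km A `km_result` from [km_logrank()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  stopifnot(inherits(km, "km_result"))
  ggplot2::ggplot(km$curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                          colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_bw() +
    ggplot2::labs(
      x = "time", y = "survival probability",
      subtitle = sprintf("log-rank p = %.3g", km$test$p)
    )
}

#' ROC curve
#'
#' @param roc Result of [roc_auc()].
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::theme_bw() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", roc$auc))
}

#' Enrichment dot plot
#'
#' @param enr Tibble from [gsea()] or [ora_hypergeometric()].
#' @param top Number of sets shown (by p-value).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enr, top = 10) {
  enr <- head(dplyr::arrange(enr, .data$p), top)
  size_var <- if ("k_overlap" %in% names(enr)) "k_overlap" else "set_size"
  ggplot2::ggplot(enr, ggplot2::aes(x = -log10(pmax(.data$p, 1e-300)),
                                    y = stats::reorder(.data$set_name, -.data$p),
                                    size = .data[[size_var]],
                                    colour = .data$q)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::theme_bw() +
    ggplot2::labs(x = "-log10 p", y = NULL)
}
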