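#' Simulate a clinical validation table
#'
#' Generates per-patient marker expression (log-normal), overall and
#' disease-free survival with an exponential baseline hazard multiplied by
#' `hazard_ratio_high_marker` for patients above the median marker, an
#' ordinal stage (I-IV) positively associated with marker expression, a
#' binary histology status, and a binary chemotherapy-resistance flag with
#' logistic dependence on the marker.
#'
#' Histology has two modes. When `contingency_counts` (a, b, c, d — the
#' marker-high positive/negative and marker-low positive/negative cells)
#' sum exactly to `clinical_n`, the emitted cross-tabulation matches those
#' counts exactly: the a+b highest-marker patients form the high group and
#' statuses are assigned by permutation within groups. Otherwise statuses
#' are drawn by odds-ratio sampling at the odds ratio implied by the four
#' counts.
#'
#' @param config A [sim_config()].
#' @param truth The `ground_truth` from [sim_counts()] (used only to name the
#'   marker after the planted regulator).
#' @param exact_contingency Force (TRUE) or forbid (FALSE) exact-table mode;
#'   default `NULL` selects it automatically when the counts sum to
#'   `clinical_n`.
#' @return A `clinical_table` tibble: `sample_id`, `marker`,
#'   `marker_expression`, `os_time`, `os_event`, `dfs_time`, `dfs_event`,
#'   `stage`, `histology_positive`, `chemo`.
#' @examples
#' cfg <- sim_config()
#' ct <- sim_clinical(cfg, sim_counts(sim_config(
#'   n_genes = 120, n_cells_per_group = 10, n_de_genes = 14,
#'   n_module_genes = 20))$truth)
#' table(ct$histology_positive, ct$marker_expression > median(ct$marker_expression))
#' @export
sim_clinical <- function(config, truth, exact_contingency = NULL) {
  config <- validate_sim_config(config)
  if (config$clinical_n <= 0)
    abort("clinical_n must be positive", class = "pathtriage_config_error")
  set.seed(sim_substream_seed(config, "clinical"))
  n <- config$clinical_n
  cc <- config$contingency_counts
  exact <- exact_contingency %||% (sum(cc) == n)
  if (isTRUE(exact_contingency) && sum(cc) != n)
    abort("contingency_counts must sum to clinical_n in exact mode",
          class = "pathtriage_config_error")

  marker <- exp(rnorm(n, 0, 1))
  high <- marker > median(marker)  # ties fall to the low group

  base_os <- 0.10
  base_dfs <- 0.15
  hr <- config$hazard_ratio_high_marker
  draw_surv <- function(rate0, horizon) {
    t <- rexp(n, rate = rate0 * ifelse(high, hr, 1))
    list(time = pmin(t, horizon), event = as.integer(t <= horizon))
  }
  os <- draw_surv(base_os, 30)
  dfs <- draw_surv(base_dfs, 30)

  stage_latent <- as.numeric(scale(log(marker))) + rnorm(n, 0, 1)
  stage <- cut(stage_latent,
               breaks = quantile(stage_latent, c(0, 0.30, 0.60, 0.85, 1)),
               labels = c("I", "II", "III", "IV"), include.lowest = TRUE)

  if (exact) {
    ord <- order(-marker)
    n_high <- cc[1] + cc[2]
    high_tab <- rep(NA_integer_, n)
    high_idx <- ord[seq_len(n_high)]
    low_idx <- ord[-seq_len(n_high)]
    high_tab[high_idx] <- sample(rep(c(1L, 0L), c(cc[1], cc[2])))
    high_tab[low_idx] <- sample(rep(c(1L, 0L), c(cc[3], cc[4])))
    histology <- high_tab
  } else {
    p_low <- (cc[3] + 0.5) / (cc[3] + cc[4] + 1)
    or <- ((cc[1] + 0.5) * (cc[4] + 0.5)) / ((cc[2] + 0.5) * (cc[3] + 0.5))
    p_high <- stats::plogis(stats::qlogis(p_low) + log(or))
    histology <- rbinom(n, 1, ifelse(high, p_high, p_low))
  }

  chemo <- rbinom(n, 1, stats::plogis(-0.5 + 0.8 * as.numeric(scale(log(marker)))))

  structure(
    tibble(
      sample_id = sprintf("PT%04d", seq_len(n)),
      marker_expression = marker,
      marker = truth$planted_regulator_id,
      os_time = os$time, os_event = os$event,
      dfs_time = dfs$time, dfs_event = dfs$event,
      stage = as.character(stage),
      histology_positive = histology,
      chemo = chemo
    ),
    class = c("clinical_table", "tbl_df", "tbl", "data.frame")
  )
}

#' Generate the full set of synthetic pipeline inputs
#'
#' Convenience wrapper running all four generators from one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `counts`, `truth`, `gene_sets`, `ppi`, `clinical`.
#' @examples
#' sim <- sim_all(sim_config(n_genes = 150, n_cells_per_group = 15,
#'                           n_de_genes = 14, n_module_genes = 25,
#'                           ppi_n_background_genes = 50))
#' names(sim)
#' @export
sim_all <- function(config = sim_config()) {
  cm <- sim_counts(config)
  list(
    counts = cm$counts,
    truth = cm$truth,
    gene_sets = sim_gene_sets(config, cm$truth),
    ppi = sim_ppi(config, cm$truth),
    clinical = sim_clinical(config, cm$truth)
  )
}
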