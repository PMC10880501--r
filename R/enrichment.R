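#' Hypergeometric over-representation analysis
#'
#' For each gene set, the one-sided upper hypergeometric tail
#' `P(X >= k)` with population = universe, successes = set members present
#' in the universe, draws = the hit list. Benjamini-Hochberg adjustment is
#' applied across sets.
#'
#' @param hits Character vector of hit genes (must lie in `universe`).
#' @param universe Character vector: the gene universe.
#' @param collection A [gene_set_collection()].
#' @return Tibble with `set_name`, `set_size`, `k_overlap`, `p`, `q`,
#'   `overlap_genes` (list-column), sorted by `p`.
#' @examples
#' gs <- gene_set_collection(list(S = letters[1:5]))
#' ora_hypergeometric(letters[1:5], letters[1:20], gs)
#' @export
ora_hypergeometric <- function(hits, universe, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  if (length(universe) == 0)
    abort("empty universe", class = "pathtriage_input_error")
  hits <- unique(hits)
  if (!all(hits %in% universe))
    abort("hits must be a subset of the universe", class = "pathtriage_input_error")
  res <- purrr::imap(collection$sets, function(s, nm) {
    s <- intersect(s, universe)
    ov <- intersect(hits, s)
    k <- length(ov)
    p <- phyper(k - 1, length(s), length(universe) - length(s),
                length(hits), lower.tail = FALSE)
    tibble(set_name = nm, set_size = length(s), k_overlap = k,
           p = p, overlap_genes = list(sort(ov)))
  })
  out <- dplyr::bind_rows(res)
  out$q <- p.adjust(out$p, method = "BH")
  dplyr::arrange(out[, c("set_name", "set_size", "k_overlap", "p", "q",
                         "overlap_genes")], .data$p, .data$set_name)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classical GSEA running sum over a ranked gene list: at in-set genes the
#' sum increases by `|score|^weight_p` normalised over the in-set genes; at
#' out-of-set genes it decreases by `1/(N - n_set)`. The enrichment score is
#' the signed maximum deviation from zero; the leading edge contains the
#' in-set genes up to (for positive ES) or from (negative ES) the extremum.
#'
#' @param ranked Tibble or data frame with columns `gene` (unique) and
#'   `score`, ordered from most positive to most negative score.
#' @param set Character vector of set members.
#' @param weight_p Score weighting exponent (0 = unweighted KS).
#' @return List with `es`, `running` (length-N running sum), and
#'   `leading_edge`; `NULL` when the set is disjoint from the ranking.
#' @examples
#' r <- tibble::tibble(gene = c("a", "b", "c", "d"), score = c(3, 2, 1, 0.5))
#' gsea_es(r, "a", weight_p = 0)$es
#' @export
gsea_es <- function(ranked, set, weight_p = 1) {
  ranked <- as_tibble(ranked)
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  if (anyDuplicated(ranked$gene))
    abort("ranked genes must be unique", class = "pathtriage_input_error")
  inset <- ranked$gene %in% set
  n <- nrow(ranked)
  nh <- sum(inset)
  if (nh == 0) return(NULL)
  w <- abs(ranked$score)^weight_p
  nr <- sum(w[inset])
  incr <- if (nr > 0) w / nr else rep(1 / nh, n)
  step <- ifelse(inset, incr, 0)
  if (n > nh) step[!inset] <- -1 / (n - nh)
  running <- cumsum(step)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) ranked$gene[seq_len(i_max)][inset[seq_len(i_max)]]
  else ranked$gene[i_max:n][inset[i_max:n]]
  list(es = es, running = running, leading_edge = leading)
}

#' Permutation GSEA over a gene-set collection
#'
#' Computes the enrichment score of every set against a ranked list, then a
#' gene-label permutation null: for each permutation, `n_set` genes are
#' redrawn at random from the ranking and the ES recomputed. The normalised
#' enrichment score is `ES / mean(|null ES| of matching sign)`; the p-value
#' is the two-sided empirical tail `(1 + #{|null| >= |ES|}) / (1 + n_perm)`;
#' q is Benjamini-Hochberg across scored sets.
#'
#' @param ranked Tibble with `gene`, `score` ordered by decreasing score.
#' @param collection A [gene_set_collection()].
#' @param n_perm Number of permutations (>= 10).
#' @param weight_p Score weighting exponent.
#' @param seed Integer seed making the permutation null reproducible.
#' @return Tibble with `set_name`, `set_size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (list-column); sets disjoint from the ranking are
#'   skipped with a warning.
#' @examples
#' r <- tibble::tibble(gene = letters[1:10], score = 10:1)
#' gs <- gene_set_collection(list(TOP = letters[1:3], MID = letters[5:7]))
#' gsea(r, gs, n_perm = 100, seed = 1)
#' @export
gsea <- function(ranked, collection, n_perm = 1000, weight_p = 1, seed = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (n_perm < 10)
    abort("n_perm must be at least 10", class = "pathtriage_config_error")
  ranked <- as_tibble(ranked)
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$score), .data$gene)
  set.seed(seed)
  n <- nrow(ranked)
  w_abs <- abs(ranked$score)^weight_p
  # lean ES on integer positions, used for the permutation null
  es_at <- function(idx) {
    wi <- w_abs[idx]
    nr <- sum(wi)
    step <- rep.int(-1 / (n - length(idx)), n)
    step[idx] <- if (nr > 0) wi / nr else 1 / length(idx)
    running <- cumsum(step)
    running[which.max(abs(running))]
  }
  rows <- purrr::imap(collection$sets, function(s, nm) {
    obs <- gsea_es(ranked, s, weight_p)
    if (is.null(obs)) {
      warn(sprintf("set '%s' is disjoint from the ranking; skipped", nm))
      return(NULL)
    }
    nh <- sum(ranked$gene %in% s)
    null_es <- vapply(seq_len(n_perm), function(i) {
      es_at(sample.int(n, nh))
    }, numeric(1))
    same_sign <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same_sign) > 0) obs$es / mean(abs(same_sign)) else NA_real_
    p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + n_perm)
    tibble(set_name = nm, set_size = nh, es = obs$es, nes = nes, p = p,
           leading_edge = list(obs$leading_edge))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$q <- p.adjust(out$p, method = "BH")
  # permutation p-values tie at the add-one floor; |NES| separates them
  dplyr::arrange(out[, c("set_name", "set_size", "es", "nes", "p", "q",
                         "leading_edge")],
                 .data$p, dplyr::desc(abs(.data$nes)), .data$set_name)
}
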