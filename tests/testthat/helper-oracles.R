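# Brute-force oracles, written independently of the package internals.

# per-cell QC by explicit loops
oracle_qc <- function(counts, mito_prefix = "MT-") {
  out <- data.frame(cell = colnames(counts), n_count = NA_real_,
                    n_feature = NA_integer_, percent_mt = NA_real_)
  for (j in seq_len(ncol(counts))) {
    v <- counts[, j]
    out$n_count[j] <- sum(v)
    out$n_feature[j] <- sum(v > 0)
    mt <- sum(v[startsWith(rownames(counts), mito_prefix)])
    out$percent_mt[j] <- if (sum(v) > 0) 100 * mt / sum(v) else 0
  }
  out
}

# all-pairs shortest paths by Floyd-Warshall on an adjacency matrix
oracle_apsp <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  dimnames(d) <- dimnames(adj)
  d
}

# unsigned TOM by triple loop
oracle_tom <- function(A) {
  n <- nrow(A)
  diag(A) <- 1
  k <- sapply(seq_len(n), function(m) sum(A[m, -m]))
  tom <- diag(n)
  for (m in seq_len(n)) for (p in seq_len(n)) {
    if (m == p) next
    l <- 0
    for (u in seq_len(n)) if (u != m && u != p) l <- l + A[m, u] * A[u, p]
    tom[m, p] <- (l + A[m, p]) / (min(k[m], k[p]) + 1 - A[m, p])
  }
  tom
}

# exact two-sided rank-sum permutation p-value (all group assignments)
oracle_exact_wilcox_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  centre <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - centre) >= abs(obs - centre) - 1e-9)
}

# GSEA running sum enumerated step by step
oracle_running_sum <- function(scores, inset, weight_p) {
  n <- length(scores)
  nh <- sum(inset)
  w <- abs(scores)^weight_p
  nr <- sum(w[inset])
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- if (inset[i]) acc + w[i] / nr else acc - 1 / (n - nh)
    run[i] <- acc
  }
  run
}

# AUC by explicit pairwise concordance
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# two-group log-rank by an explicit observed/expected/variance ledger
oracle_logrank <- function(time, event, group1) {
  times <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# a small deterministic count_matrix fixture
tiny_counts <- function(n_genes = 12, n_cells = 8, seed = 42,
                        mito = TRUE, groups = NULL) {
  set.seed(seed)
  genes <- c(if (mito) "MT-1", paste0("G", seq_len(n_genes - mito)))
  counts <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells,
                   dimnames = list(genes, paste0("c", seq_len(n_cells))))
  if (is.null(groups)) groups <- rep(c("tumor", "normal"), length.out = n_cells)
  count_matrix(counts, tibble::tibble(
    cell = colnames(counts), sample = "s1", group = groups
  ))
}

# small config for fast planted-truth runs; overrides win
small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 300, n_cells_per_group = 60, n_de_genes = 20,
               n_module_genes = 40, ppi_n_background_genes = 100,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
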