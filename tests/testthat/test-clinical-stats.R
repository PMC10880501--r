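test_that("pearson correlation matches the covariance formula", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(0.5, 2.9, 1.1, 4.8, 3.0)
  res <- pearson_r(x, y)
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_ref)
  ref <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ref$estimate))
  expect_equal(res$p, ref$p.value)
  # affine invariance with positive slope
  expect_equal(pearson_r(2 * x + 3, y)$r, res$r)
  expect_error(pearson_r(rep(1, 5), y), class = "pathtriage_input_error")
  expect_error(pearson_r(1:2, 1:2), class = "pathtriage_input_error")
})

test_that("welch comparison matches the closed form and flags stars", {
  x1 <- c(1.1, 2.3, 3.1)
  x2 <- c(4.0, 5.2, 6.9)
  res <- group_compare(c(x1, x2), rep(c("a", "b"), each = 3))
  v1 <- var(x1) / 3
  v2 <- var(x2) / 3
  t_ref <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  df_ref <- (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2)
  expect_equal(res$t, t_ref)
  expect_equal(res$df, df_ref)
  expect_equal(res$p, 2 * pt(-abs(t_ref), df_ref))

  same <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_gt(same$p, 0.99)

  const <- group_compare(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(const$p, 1)
  expect_error(group_compare(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3)),
               class = "pathtriage_input_error")
})

test_that("welch test has power at one-sd shifts", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    group_compare(c(rnorm(50), rnorm(50, 1)),
                  rep(c("a", "b"), each = 50))$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("log-rank agrees with a hand ledger and survdiff", {
  # 6-subject worked example, groups split by marker at the median
  ct <- tibble::tibble(
    marker_expression = c(10, 9, 8, 1, 2, 3),
    os_time = c(2, 4, 6, 1, 3, 5),
    os_event = c(1, 1, 0, 1, 1, 1)
  )
  res <- km_logrank(ct, "OS")
  ref <- oracle_logrank(ct$os_time, ct$os_event,
                        ct$marker_expression > median(ct$marker_expression))
  expect_equal(res$test$logrank_stat, ref, tolerance = 1e-10)
  expect_equal(res$test$p, pchisq(ref, 1, lower.tail = FALSE))

  # identical survival experience in both groups: statistic 0
  ct0 <- tibble::tibble(
    marker_expression = rep(c(1, 10), each = 4),
    os_time = rep(c(1, 2, 3, 4), 2),
    os_event = rep(1, 8)
  )
  expect_lt(km_logrank(ct0, "OS")$test$logrank_stat, 1e-10)
})

test_that("log-rank is invariant to monotone time transforms and label swap", {
  set.seed(1)
  ct <- tibble::tibble(
    marker_expression = rnorm(40),
    os_time = rexp(40), os_event = rbinom(40, 1, 0.8)
  )
  a <- km_logrank(ct, "OS")$test$logrank_stat
  ct2 <- ct
  ct2$os_time <- ct$os_time^3  # strictly monotone
  expect_equal(km_logrank(ct2, "OS")$test$logrank_stat, a)
  ct3 <- ct
  ct3$marker_expression <- -ct$marker_expression
  b <- km_logrank(ct3, "OS")$test$logrank_stat
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("survival power under the planted hazard ratio", {
  truth <- sim_counts(small_config())$truth
  hits <- vapply(1:20, function(s) {
    ct <- sim_clinical(sim_config(clinical_n = 300, seed = s,
                                  hazard_ratio_high_marker = 2.5),
                       truth, exact_contingency = FALSE)
    km_logrank(ct, "OS")$test$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pearson chi-square satisfies both computation routes", {
  res <- chisq_2x2(matrix(c(66, 45, 64, 85), 2))
  expect_equal(round(res$chi_square, 3), 6.933)
  expect_equal(res$df, 1L)

  set.seed(2)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    res <- chisq_2x2(tab)
    # route 1: cellwise sum of (O - E)^2 / E
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chi_square, sum((tab - e)^2 / e), tolerance = 1e-10)
    # route 2: the base-R implementation without correction
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$chi_square, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(chisq_2x2(matrix(10, 2, 2))$chi_square, 0)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)),
               class = "pathtriage_input_error")
  # Yates correction is available but off by default
  expect_lt(chisq_2x2(matrix(c(66, 45, 64, 85), 2), correct = TRUE)$chi_square,
            6.933)
})

test_that("auc equals the pairwise concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(3)
  for (i in 1:10) {
    scores <- round(rnorm(30), 1)  # rounding forces some ties
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  # complement identity for tie-free scores
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.4)
  expect_equal(roc_auc(scores, labels)$auc + roc_auc(-scores, labels)$auc, 1)
  # null scores give AUC near 1/2
  set.seed(4)
  auc_null <- roc_auc(rnorm(4000), rbinom(4000, 1, 0.5))$auc
  expect_lt(abs(auc_null - 0.5), 0.05)
  expect_error(roc_auc(1:5, rep(1, 5)), class = "pathtriage_input_error")
})

test_that("auc agrees with an independent roc implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.5)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref)
})

test_that("roc curve endpoints and monotonicity", {
  set.seed(6)
  r <- roc_auc(rnorm(40), rbinom(40, 1, 0.5))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("stage association reports means and adjacent-stage tests", {
  truth <- sim_counts(small_config())$truth
  ct <- sim_clinical(sim_config(clinical_n = 400, seed = 7), truth)
  sa <- stage_association(ct)
  expect_setequal(sa$summary$stage, c("I", "II", "III", "IV"))
  expect_equal(nrow(sa$tests), 3)
  # marker rises with stage by construction
  expect_gt(sa$summary$mean[sa$summary$stage == "IV"],
            sa$summary$mean[sa$summary$stage == "I"])
})
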