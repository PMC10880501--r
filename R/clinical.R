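#' Pearson correlation with a t-test p-value
#'
#' Sample Pearson correlation and the two-sided p-value from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, non-constant).
#' @return Tibble with `r`, `p`, `n`.
#' @examples
#' pearson_r(1:10, (1:10) + rnorm(10, 0, 0.1))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("x and y must have equal length >= 3", class = "pathtriage_input_error")
  if (sd(x) == 0 || sd(y) == 0)
    abort("correlation undefined for constant input",
          class = "pathtriage_input_error")
  n <- length(x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tibble(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Two-group Welch comparison
#'
#' Welch two-sided t-test between two groups, with the conventional
#' significance stars (* p < .05, ** p < .01, *** p < .001).
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping vector.
#' @return Tibble with `group_1`, `group_2`, `mean_1`, `mean_2`,
#'   `difference`, `t`, `df`, `p`, `stars`.
#' @export
group_compare <- function(values, labels) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2)
    abort("labels must contain exactly two groups", class = "pathtriage_input_error")
  x1 <- values[labels == lv[1]]
  x2 <- values[labels == lv[2]]
  if (length(x1) < 2 || length(x2) < 2)
    abort("each group needs at least 2 observations",
          class = "pathtriage_input_error")
  if (sd(x1) == 0 && sd(x2) == 0) {
    if (mean(x1) == mean(x2)) {
      return(tibble(group_1 = lv[1], group_2 = lv[2], mean_1 = mean(x1),
                    mean_2 = mean(x2), difference = 0, t = 0,
                    df = NA_real_, p = 1, stars = ""))
    }
    abort("zero variance in both groups with unequal means",
          class = "pathtriage_input_error")
  }
  tt <- stats::t.test(x1, x2)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  tibble(group_1 = lv[1], group_2 = lv[2],
         mean_1 = mean(x1), mean_2 = mean(x2),
         difference = mean(x1) - mean(x2),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = p, stars = stars)
}

#' Kaplan-Meier comparison at the marker median split
#'
#' Splits samples at the median of `marker_expression` (ties to the low
#' group), fits Kaplan-Meier curves per group, and compares them with the
#' two-group log-rank test (sum over event times of observed minus expected
#' events with hypergeometric variance; p from chi-square with 1 df).
#'
#' @param ct A clinical table (tibble) with `marker_expression` and the
#'   endpoint columns.
#' @param endpoint `"OS"` (uses `os_time`/`os_event`) or `"DFS"`
#'   (`dfs_time`/`dfs_event`).
#' @return A `km_result` list: `test` (tibble: `logrank_stat`, `df`, `p`,
#'   `split_value`, `n_high`, `n_low`) and `curves` (tibble of step-function
#'   points: `group`, `time`, `surv`).
#' @export
km_logrank <- function(ct, endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  time <- if (endpoint == "OS") ct$os_time else ct$dfs_time
  event <- if (endpoint == "OS") ct$os_event else ct$dfs_event
  if (sum(event) < 2)
    abort("need at least 2 events", class = "pathtriage_input_error")
  split_value <- median(ct$marker_expression)
  grp <- ifelse(ct$marker_expression > split_value, "high", "low")
  if (length(unique(grp)) < 2)
    abort("median split produced an empty group",
          class = "pathtriage_input_error")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- tibble(
    group = sub("^grp=", "", strata),
    time = fit$time,
    surv = fit$surv,
    n_risk = fit$n.risk,
    n_event = fit$n.event
  )
  structure(
    list(
      test = tibble(
        endpoint = endpoint,
        logrank_stat = unname(sd$chisq), df = 1, p = p,
        split_value = split_value,
        n_high = sum(grp == "high"), n_low = sum(grp == "low")
      ),
      curves = curves
    ),
    class = "km_result"
  )
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> %s: log-rank chi^2 = %.3f, p = %.4g (n = %d/%d)\n",
              x$test$endpoint, x$test$logrank_stat, x$test$p,
              x$test$n_high, x$test$n_low))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' The uncorrected Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of freedom;
#' a Yates continuity correction is available by flag but off by default.
#'
#' @param table 2x2 matrix of non-negative counts (all margins > 0).
#' @param correct Apply the Yates continuity correction.
#' @return Tibble with `chi_square`, `df`, `p`, `n`.
#' @examples
#' chisq_2x2(matrix(c(66, 45, 64, 85), 2))
#' @export
chisq_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0))
    abort("need a 2x2 table of non-negative counts",
          class = "pathtriage_input_error")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort("all margins must be positive", class = "pathtriage_input_error")
  n <- sum(table)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / (sum(table[1, ]) * sum(table[2, ]) *
                         sum(table[, 1]) * sum(table[, 2]))
  tibble(chi_square = stat, df = 1L,
         p = pchisq(stat, 1, lower.tail = FALSE), n = n)
}

#' ROC curve and AUC by the Mann-Whitney concordance
#'
#' AUC equals the probability that a random positive scores above a random
#' negative, with ties counted 0.5 (computed from the rank-sum). The curve
#' gives (FPR, TPR) at every distinct score threshold.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical); both classes must be
#'   present.
#' @return List with `auc` and `curve` (tibble: `threshold`, `fpr`, `tpr`).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    abort("both classes must be present", class = "pathtriage_input_error")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- purrr::map_dfr(thresholds, function(th) {
    pred <- scores >= th
    tibble(threshold = th,
           fpr = sum(pred & labels == 0) / n_neg,
           tpr = sum(pred & labels == 1) / n_pos)
  })
  list(auc = auc, curve = curve)
}

#' Marker-by-stage summary with adjacent-stage tests
#'
#' Group means with SD per stage plus Welch tests between adjacent stages.
#'
#' @param ct Clinical table with `marker_expression` and `stage`.
#' @return List with `summary` (tibble per stage) and `tests` (tibble of
#'   adjacent-stage Welch comparisons).
#' @export
stage_association <- function(ct) {
  stages <- sort(unique(as.character(ct$stage)))
  summary <- dplyr::summarise(
    dplyr::group_by(tibble(stage = as.character(ct$stage),
                           x = ct$marker_expression), .data$stage),
    n = dplyr::n(), mean = mean(.data$x), sd = sd(.data$x), .groups = "drop"
  )
  tests <- purrr::map_dfr(seq_len(length(stages) - 1), function(i) {
    sel <- as.character(ct$stage) %in% stages[c(i, i + 1)]
    res <- group_compare(ct$marker_expression[sel],
                         as.character(ct$stage)[sel])
    res
  })
  list(summary = summary, tests = tests)
}
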