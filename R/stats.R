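#' Absolute risk difference with Wald interval
#'
#' Group rates are first rounded to one decimal percentage point and then
#' differenced, matching report-style arithmetic in which printed rates
#' are subtracted; the unrounded difference is also returned. The 95%
#' Wald interval is computed on the unrounded difference:
#' d +/- 1.96 * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2).
#'
#' @param x1,n1 Events and total in group 1.
#' @param x2,n2 Events and total in group 2.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `rate1`, `rate2` (rounded percentages),
#'   `diff` (round-first, percentage points), `diff_unrounded`,
#'   `conf_low`, `conf_high`.
#' @examples
#' risk_difference(29, 193, 7, 52)  # 15.0 - 13.5 = 1.5 points
#' @export
risk_difference <- function(x1, n1, x2, n2, conf_level = 0.95) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  r1 <- round(100 * p1, 1)
  r2 <- round(100 * p2, 1)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  d <- 100 * (p1 - p2)
  tibble(
    rate1 = r1, rate2 = r2,
    diff = r1 - r2, diff_unrounded = d,
    conf_low = d - z * 100 * se, conf_high = d + z * 100 * se
  )
}

#' Difference in medians with percentile bootstrap interval
#'
#' Point estimate is `median(x1) - median(x2)`; the interval is a seeded
#' percentile bootstrap resampling within each group.
#'
#' @param x1,x2 Non-empty numeric samples.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed RNG seed for the resampling.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `median1`, `median2`, `diff`, `conf_low`,
#'   `conf_high`.
#' @examples
#' median_difference(c(30, 33.4, 40), c(18, 20.8, 25), n_boot = 200, seed = 1)
#' @export
median_difference <- function(x1, x2, n_boot = 2000, seed = 1,
                              conf_level = 0.95) {
  if (!length(x1) || !length(x2)) abort("empty sample")
  m1 <- median(x1); m2 <- median(x2)
  boots <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      median(sample(x1, replace = TRUE)) - median(sample(x2, replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - conf_level) / 2
  ci <- unname(quantile(boots, c(a, 1 - a), type = 7))
  tibble(median1 = m1, median2 = m2, diff = m1 - m2,
         conf_low = ci[1], conf_high = ci[2])
}

# two-sided exact p for a 2x2 table; the single Fisher path of the package
fisher_p <- function(tab) {
  min(stats::fisher.test(tab)$p.value, 1)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Two-group hypothesis test dispatcher
#'
#' Continuous variables: Wilcoxon rank-sum with normal approximation and
#' tie correction. Categorical variables (given as a contingency table
#' with groups in columns): Fisher's exact test for 2x2 tables when any
#' expected cell is below 5, else chi-square with continuity correction;
#' k x 2 tables use chi-square. Degenerate tables (a zero margin) give
#' `p_value = NA` with method "not applicable".
#'
#' @param x Numeric vector (continuous) or a 2-column matrix/table of
#'   counts (categorical).
#' @param group For continuous `x`, a 2-level grouping vector.
#' @return One-row tibble: `statistic`, `p_value`, `method`.
#' @examples
#' two_group_test(matrix(c(5, 5, 5, 5), 2))
#' two_group_test(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
two_group_test <- function(x, group = NULL) {
  if (is.matrix(x) || is.table(x)) {
    tab <- as.matrix(x)
    stopifnot(ncol(tab) == 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(tibble(statistic = NA_real_, p_value = NA_real_,
                    method = "not applicable"))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (nrow(tab) == 2 && any(expected < 5)) {
      return(tibble(statistic = NA_real_, p_value = fisher_p(tab),
                    method = "Fisher exact"))
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = nrow(tab) == 2))
    return(tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                  method = "chi-square"))
  }
  g <- as.factor(group)
  stopifnot(nlevels(g) == 2)
  ht <- suppressWarnings(
    stats::wilcox.test(x[g == levels(g)[1]], x[g == levels(g)[2]],
                       exact = FALSE, correct = TRUE))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Wilcoxon rank-sum")
}
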