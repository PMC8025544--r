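# Cohort-level statistics: mean +/- SD [range] summaries and the Wilcoxon
# rank-sum subgroup comparison.

#' Mean, SD and range over cohort cases
#'
#' Sample mean, sample SD (n-1 denominator), minimum and maximum. A single
#' value gives SD 0 with `sd_defined = FALSE`.
#'
#' @param values numeric vector, length >= 1.
#' @return A one-row tibble: n, mean, sd, min, max, sd_defined.
#' @export
summarize_cohort <- function(values) {
  if (!length(values)) stop("no values to summarize", call. = FALSE)
  n <- length(values)
  tibble::tibble(n = n, mean = mean(values),
                 sd = if (n > 1) stats::sd(values) else 0,
                 min = min(values), max = max(values),
                 sd_defined = n > 1)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact null distribution when the pooled sample has at most 12
#' observations and no ties; otherwise the normal approximation with
#' continuity and tie correction. Two-sided throughout.
#'
#' @param group_a,group_b non-empty numeric vectors (independent samples).
#' @return A `rank_sum_result`: `u` (Mann-Whitney U for group_a), `p`
#'   (two-sided), `method` (`"exact"` or `"normal-approximation"`),
#'   `n_a`, `n_b`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(group_a); n2 <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (n1 + n2) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            exact = exact, correct = TRUE))
  structure(list(u = unname(wt$statistic), p = wt$p.value,
                 method = if (exact) "exact" else "normal-approximation",
                 n_a = n1, n_b = n2),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("<rank_sum_result> U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$u, x$n_a, x$n_b, x$p, x$method))
  invisible(x)
}

#' @export
tidy.rank_sum_result <- function(x, ...) {
  tibble::tibble(u = x$u, p = x$p, method = x$method, n_a = x$n_a,
                 n_b = x$n_b)
}
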