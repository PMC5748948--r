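#' Pooled survival summary over replicates
#'
#' Summarizes embryo survival for one experimental condition from replicate
#' counts of embryos alive at 72 h versus embryos injected. The pooled
#' percentage is `100 * sum(alive) / sum(injected)`; the spread is the
#' sample standard deviation (n - 1 denominator) of the per-replicate
#' survival proportions on the 0--1 scale, reported as `NA` for a single
#' replicate.
#'
#' @param alive integer vector: embryos alive at 72 h per replicate.
#' @param injected integer vector: embryos injected per replicate
#'   (same length, all positive, `alive <= injected`).
#' @param condition optional condition label carried through to the result.
#' @return A `survival_summary`: list with `pooled_percent`,
#'   `sd_of_proportions`, `n_replicates`, `total_alive`, `total_injected`,
#'   `condition`.
#' @examples
#' survival_summary(c(12, 47, 44), c(12, 48, 48))
#' @export
survival_summary <- function(alive, injected, condition = NULL) {
  if (length(alive) != length(injected) || length(alive) < 1L)
    stop("`alive` and `injected` must be equal-length vectors with >= 1 replicate",
         call. = FALSE)
  if (anyNA(alive) || anyNA(injected))
    stop("replicate counts must not contain NA", call. = FALSE)
  if (any(injected <= 0))
    stop("every replicate must have injected > 0", call. = FALSE)
  if (any(alive < 0) || any(alive > injected))
    stop("need 0 <= alive <= injected in every replicate", call. = FALSE)
  props <- alive / injected
  structure(list(
    pooled_percent = 100 * sum(alive) / sum(injected),
    sd_of_proportions = if (length(props) > 1L) stats::sd(props) else NA_real_,
    n_replicates = length(alive),
    total_alive = sum(alive),
    total_injected = sum(injected),
    condition = condition
  ), class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf("<survival_summary>%s %d/%d alive over %d replicate(s): %.3f%% +/- %s\n",
              if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$total_alive, x$total_injected, x$n_replicates,
              x$pooled_percent,
              if (is.na(x$sd_of_proportions)) "NA"
              else sprintf("%.3f", x$sd_of_proportions)))
  invisible(x)
}

#' IQR outlier filter (Tukey fences, spreadsheet quartiles)
#'
#' Splits a vector into kept values and outliers using fences
#' `[Q1 - k * IQR, Q3 + k * IQR]`. Quartiles use linear interpolation of
#' order statistics (the "inclusive" method -- R's `type = 7`, identical to
#' spreadsheet `QUARTILE`), so results match the spreadsheet-based outlier
#' screens this workflow descends from. Order is preserved within each
#' output.
#'
#' @param values numeric vector, length >= 4.
#' @param k fence multiplier (default 1.5, the conventional Tukey value).
#' @return list with `kept`, `outliers`, `q1`, `q3`, `fences`.
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100))
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) < 4L)
    stop("iqr_filter needs at least 4 values (got ", length(values), ")",
         call. = FALSE)
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  fences <- c(q[1L] - k * iqr, q[2L] + k * iqr)
  out <- values < fences[1L] | values > fences[2L]
  list(kept = values[!out], outliers = values[out],
       q1 = q[1L], q3 = q[2L], fences = fences)
}

#' Two-group comparison gated on homoscedasticity
#'
#' Implements the decision rule used for comparing per-embryo proliferation
#' indices between conditions: equality of variances is first assessed with
#' Levene's test on absolute deviations from the group medians (the
#' Brown-Forsythe variant, robust to non-normality) at level 0.05. If the
#' groups are homoscedastic a two-sample Student's t-test with pooled
#' variance is applied; otherwise the non-parametric one-factor rank test
#' (Kruskal-Wallis, which with two groups is equivalent to a Wilcoxon
#' rank-sum test with tie correction) is used.
#'
#' @param a,b numeric vectors, each of length >= 3 (after any outlier
#'   filtering).
#' @param alpha significance level, 0.05 or 0.01.
#' @return A `comparison_result`: list with `test_used` (`"student_t"` or
#'   `"kruskal_wallis"`), `homoscedastic`, `levene_p`, `statistic`,
#'   `p_value`, `alpha`, `significant`.
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(20, 0.5, 0.1), rnorm(20, 2.5, 0.1), alpha = 0.01)
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 values (got ", length(a), " and ",
         length(b), ")", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("groups must not contain NA", call. = FALSE)
  if (!alpha %in% c(0.05, 0.01))
    stop("`alpha` must be 0.05 or 0.01", call. = FALSE)
  lev_p <- levene_p_value(a, b)
  homoscedastic <- is.na(lev_p) || lev_p >= 0.05
  if (homoscedastic) {
    if (stats::sd(c(a, b)) == 0) {
      # both groups constant and equal: no evidence of any difference
      statistic <- 0; p_value <- 1
    } else {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      statistic <- unname(ht$statistic); p_value <- ht$p.value
    }
    test_used <- "student_t"
  } else {
    ht <- stats::kruskal.test(list(a, b))
    statistic <- unname(ht$statistic); p_value <- ht$p.value
    test_used <- "kruskal_wallis"
  }
  structure(list(test_used = test_used, homoscedastic = homoscedastic,
                 levene_p = lev_p, statistic = statistic, p_value = p_value,
                 alpha = alpha, significant = p_value < alpha),
            class = "comparison_result")
}

# Brown-Forsythe / Levene: one-way ANOVA F on |x - group median|
levene_p_value <- function(a, b) {
  za <- abs(a - stats::median(a))
  zb <- abs(b - stats::median(b))
  z <- c(za, zb)
  g <- c(rep(1L, length(za)), rep(2L, length(zb)))
  n <- length(z); k <- 2L
  gm <- mean(z)
  ma <- mean(za); mb <- mean(zb)
  ss_between <- length(za) * (ma - gm)^2 + length(zb) * (mb - gm)^2
  ss_within <- sum((za - ma)^2) + sum((zb - mb)^2)
  if (ss_within == 0) {
    if (ss_between == 0) return(NA_real_)  # all deviations identical
    return(0)                              # spreads differ with no noise
  }
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (homoscedastic: %s, Levene p = %s)\n",
              x$test_used, x$homoscedastic,
              if (is.na(x$levene_p)) "NA" else format.pval(x$levene_p)),
      sprintf("  statistic = %.4f, p = %s, %ssignificant at alpha = %g\n",
              x$statistic, format.pval(x$p_value),
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}
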