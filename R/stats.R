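#' Per-case summary of segment geometry
#'
#' Mean, sample standard deviation (n - 1 denominator) and n for total
#' curvature, orphan-neurite curvature, and signed torsion, one row per
#' case: the layout of a per-case geometric-parameter table.
#'
#' @param per_segment A tibble of per-segment geometry (needs `case_id`,
#'   `mean_curvature`, `mean_torsion`, `is_orphan`).
#' @param case_id Summarise one case only; `NULL` summarises all.
#' @return A tibble with columns `case_id`, `curvature_mean`,
#'   `curvature_sd`, `curvature_n`, `orphan_curvature_mean`,
#'   `orphan_curvature_sd`, `orphan_curvature_n`, `torsion_mean`,
#'   `torsion_sd`, `torsion_n`.
#' @export
summarize_case <- function(per_segment, case_id = NULL) {
  stopifnot(is.data.frame(per_segment))
  if (!is.null(case_id)) {
    per_segment <- per_segment[per_segment$case_id %in% case_id, ]
  }
  if (nrow(per_segment) == 0) abort("no segments for the requested case")
  stat3 <- function(x) {
    x <- x[!is.na(x)]
    list(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
         n = length(x))
  }
  per_segment %>%
    group_by(.data$case_id) %>%
    summarise(
      curvature_mean = stat3(.data$mean_curvature)$mean,
      curvature_sd = stat3(.data$mean_curvature)$sd,
      curvature_n = stat3(.data$mean_curvature)$n,
      orphan_curvature_mean =
        stat3(.data$mean_curvature[.data$is_orphan])$mean,
      orphan_curvature_sd = stat3(.data$mean_curvature[.data$is_orphan])$sd,
      orphan_curvature_n = stat3(.data$mean_curvature[.data$is_orphan])$n,
      torsion_mean = stat3(.data$mean_torsion)$mean,
      torsion_sd = stat3(.data$mean_torsion)$sd,
      torsion_n = stat3(.data$mean_torsion)$n,
      .groups = "drop")
}

#' Relative-frequency histogram
#'
#' Left-closed, right-open bins of fixed width anchored at 0 (matching a
#' per-0.1-micrometre^-1 binning of curvature); frequencies sum to 1.
#'
#' @param values Numeric vector (>= 1 value; `NA` dropped).
#' @param bin_width Bin width (default 0.1).
#' @return A tibble: `bin_left`, `bin_right`, `count`, `frequency`.
#' @export
histogram_relative <- function(values, bin_width = 0.1) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1, bin_width > 0)
  k <- floor(values / bin_width)
  tab <- table(k)
  ks <- as.integer(names(tab))
  tibble(bin_left = ks * bin_width,
         bin_right = (ks + 1) * bin_width,
         count = as.integer(tab),
         frequency = as.integer(tab) / length(values))
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction and the chi-squared
#' approximation on k - 1 degrees of freedom (the standard large-sample
#' treatment). Typical use: per-segment curvatures as observations, cases as
#' groups, to ask whether the curvature median differs between cases. All
#' values identical gives H = 0, p = 1.
#'
#' @param groups A list of numeric vectors, or a data frame plus `value` /
#'   `group` column names.
#' @param value,group Column names when `groups` is a data frame.
#' @return A tibble: `statistic` (H), `df`, `p.value`, `method`.
#' @export
kruskal_wallis <- function(groups, value = "value", group = "group") {
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]])
  }
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) {
    return(tibble(statistic = 0, df = length(groups) - 1, p.value = 1,
                  method = "Kruskal-Wallis rank sum test"))
  }
  ht <- kruskal.test(groups)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, method = "Kruskal-Wallis rank sum test")
}

#' Welch's unequal-variance t-test on per-case means
#'
#' Two-sided Welch t with Welch-Satterthwaite degrees of freedom; the
#' standard test for a four-versus-four comparison of per-case mean
#' curvatures. Zero variance in both groups with equal means returns p = 1.
#'
#' @param a,b Numeric vectors of per-case means (>= 2 each).
#' @return A tibble: `statistic` (t), `df`, `p.value`, `mean_a`, `mean_b`,
#'   `method`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(statistic = 0, df = length(a) + length(b) - 2,
                    p.value = 1, mean_a = mean(a), mean_b = mean(b),
                    method = "Welch two-sample t-test"))
    }
    abort("zero variance in both groups with unequal means")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
         method = "Welch two-sample t-test")
}

#' Between-group contrast of per-case means
#'
#' Unweighted group means over cases (every case counts once, regardless of
#' how many segments it contributed), their ratio, the percent increase
#' `(ratio - 1) * 100`, and the Welch test on the per-case means.
#'
#' @param case_means_a,case_means_b Numeric vectors of per-case means; group
#'   A is the numerator.
#' @param labels Length-2 character, names of groups A and B.
#' @return An object of class `group_contrast`; see [tidy.group_contrast()]
#'   and [glance.group_contrast()].
#' @export
group_contrast <- function(case_means_a, case_means_b,
                           labels = c("A", "B")) {
  stopifnot(length(case_means_a) >= 1, length(case_means_b) >= 1)
  ma <- mean(case_means_a); mb <- mean(case_means_b)
  if (mb == 0) abort("zero denominator group mean")
  test <- if (length(case_means_a) >= 2 && length(case_means_b) >= 2) {
    welch_t(case_means_a, case_means_b)
  }
  structure(list(mean_a = ma, mean_b = mb, ratio = ma / mb,
                 percent_increase = (ma / mb - 1) * 100,
                 labels = labels, case_means_a = case_means_a,
                 case_means_b = case_means_b, test = test),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat("<group_contrast>", x$labels[1], "vs", x$labels[2], "\n")
  cat(sprintf("  means: %.4g vs %.4g  ratio: %.3f  increase: %.1f%%\n",
              x$mean_a, x$mean_b, x$ratio, x$percent_increase))
  if (!is.null(x$test)) {
    cat(sprintf("  Welch t = %.3f, df = %.2f, p = %.3g\n",
                x$test$statistic, x$test$df, x$test$p.value))
  }
  invisible(x)
}

#' Tidy a group contrast
#'
#' @param x A [group_contrast()].
#' @param ... Unused.
#' @return One row per group with its unweighted mean and case count.
#' @export
tidy.group_contrast <- function(x, ...) {
  tibble(group = x$labels,
         mean = c(x$mean_a, x$mean_b),
         n_cases = c(length(x$case_means_a), length(x$case_means_b)))
}

#' One-row summary of a group contrast
#'
#' @param x A [group_contrast()].
#' @param ... Unused.
#' @return A tibble with `ratio`, `percent_increase`, and the Welch test
#'   statistic, df and p-value (NA when a group has a single case).
#' @export
glance.group_contrast <- function(x, ...) {
  tibble(ratio = x$ratio, percent_increase = x$percent_increase,
         statistic = if (!is.null(x$test)) x$test$statistic else NA_real_,
         df = if (!is.null(x$test)) x$test$df else NA_real_,
         p.value = if (!is.null(x$test)) x$test$p.value else NA_real_)
}
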