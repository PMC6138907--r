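# Shared rank-based comparison helpers. Both wrap the tie-corrected normal
# approximation (no continuity correction) so that identical groups give
# p = 1 exactly; the study applied no multiplicity adjustment and neither do
# these helpers (adjust downstream with p.adjust if wanted).

rank_sum_test <- function(a, b, what = "value") {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  structure(list(what = what,
                 n_a = length(a), n_b = length(b),
                 median_a = stats::median(a), median_b = stats::median(b),
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = "Mann-Whitney rank-sum (two-sided, tie-corrected)"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s comparison (%s)\n", x$what, x$method))
  cat(sprintf("  group A: n = %d, median = %.4g\n", x$n_a, x$median_a))
  cat(sprintf("  group B: n = %d, median = %.4g\n", x$n_b, x$median_b))
  cat(sprintf("  W = %.4g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Compare a per-case quantity between groups of cases
#'
#' Dispatches on the number of groups: Mann-Whitney rank-sum for two groups,
#' Kruskal-Wallis for three or more — the procedure used for comparing cell
#' densities across lymphoma subtypes or stages. Raw (unadjusted) p-values
#' are reported.
#'
#' @param values Numeric vector, one value per case.
#' @param grouping Factor or character vector of group labels, same length.
#' @return List of class `group_test`: test used, statistic, p-value, group
#'   medians.
#' @export
group_compare <- function(values, grouping) {
  grouping <- as.factor(grouping)
  if (length(values) != length(grouping)) {
    stop("values and grouping have different lengths", call. = FALSE)
  }
  counts <- table(grouping)
  if (length(counts) < 2) stop("need at least 2 groups", call. = FALSE)
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    stop(sprintf("group(s) with zero cases: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  medians <- tapply(values, grouping, stats::median)
  if (length(counts) == 2) {
    lv <- levels(grouping)
    rt <- rank_sum_test(values[grouping == lv[1]], values[grouping == lv[2]])
    out <- list(test = "Mann-Whitney", statistic = rt$statistic,
                p_value = rt$p_value, medians = medians)
  } else {
    kw <- stats::kruskal.test(values, grouping)
    out <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                p_value = kw$p.value, medians = medians)
  }
  structure(out, class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g (unadjusted)\n",
              x$test, x$statistic, x$p_value))
  for (g in names(x$medians)) {
    cat(sprintf("  median[%s] = %.4g\n", g, x$medians[[g]]))
  }
  invisible(x)
}
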