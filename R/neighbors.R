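#' Cross-type nearest-neighbour distances
#'
#' For every query cell, the exact Euclidean distance to the nearest target
#' cell (e.g. from each Ki-67-negative PD1-high T-cell to the nearest
#' Ki-67+ cell). Computed by a plane sweep over targets sorted by x, which
#' returns distances identical to the brute-force O(n m) scan; a query
#' coincident with a target has distance 0.
#'
#' @param query,target Data frames with `x`, `y` coordinates (um); both
#'   non-empty. Queries should already exclude the target phenotype (gate
#'   Ki-67-negative queries upstream) so no cell measures distance to
#'   itself.
#' @param query_label,target_label Optional phenotype tags for reporting.
#' @return Object of class `nn_result`: `distances` (per query cell, query
#'   order), `n_query`, `n_target`, `median`, labels.
#' @examples
#' q <- data.frame(x = 0, y = 0)
#' t <- data.frame(x = c(3, 6), y = c(4, 8))
#' cross_nn_distances(q, t)$distances # 5
#' @export
cross_nn_distances <- function(query, target, query_label = NA_character_,
                               target_label = NA_character_) {
  query <- as.data.frame(query)
  target <- as.data.frame(target)
  if (nrow(query) == 0) stop("empty query set", call. = FALSE)
  if (nrow(target) == 0) stop("empty target set", call. = FALSE)
  ord <- order(target$x)
  d <- cross_nn_sweep(as.numeric(query$x), as.numeric(query$y),
                      as.numeric(target$x[ord]), as.numeric(target$y[ord]))
  structure(list(distances = d, n_query = nrow(query),
                 n_target = nrow(target), median = stats::median(d),
                 query_label = query_label, target_label = target_label),
            class = "nn_result")
}

#' @export
print.nn_result <- function(x, ...) {
  lab <- function(l) if (is.na(l)) "?" else l
  cat(sprintf("nearest-neighbour distances %s -> %s: %d queries, %d targets\n",
              lab(x$query_label), lab(x$target_label), x$n_query, x$n_target))
  cat(sprintf("  median %.2f um (IQR %.2f-%.2f)\n", x$median,
              stats::quantile(x$distances, 0.25),
              stats::quantile(x$distances, 0.75)))
  invisible(x)
}

#' Subsample query cells
#'
#' Uniform random subsample without replacement, seeded, optionally
#' stratified by case with proportional allocation (largest-remainder
#' rounding so exactly `k` cells are drawn). Mirrors the practice of
#' capping nearest-neighbour analyses at a fixed number of cells sampled
#' across cases.
#'
#' @param query Data frame of query cells.
#' @param k Number of cells to keep; must not exceed the population.
#' @param seed Optional integer seed.
#' @param strata Optional case labels (length `nrow(query)`) for
#'   proportional stratified sampling.
#' @return The sampled rows of `query` (original order preserved).
#' @export
sample_queries <- function(query, k, seed = NULL, strata = NULL) {
  n <- nrow(query)
  if (k > n) {
    stop(sprintf("cannot sample %d from %d cells without replacement", k, n),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(strata)) {
    idx <- sort(sample.int(n, k))
    return(query[idx, , drop = FALSE])
  }
  strata <- as.factor(strata)
  stopifnot(length(strata) == n)
  sizes <- table(strata)
  exact <- as.numeric(sizes) * k / n
  alloc <- floor(exact)
  remainder <- k - sum(alloc)
  if (remainder > 0) {
    extra <- order(exact - alloc, decreasing = TRUE)[seq_len(remainder)]
    alloc[extra] <- alloc[extra] + 1
  }
  idx <- unlist(lapply(seq_along(sizes), function(i) {
    in_stratum <- which(strata == names(sizes)[i])
    in_stratum[sample.int(length(in_stratum), alloc[i])]
  }))
  query[sort(idx), , drop = FALSE]
}

#' Compare two nearest-neighbour distance samples
#'
#' Medians plus a two-sided Mann-Whitney rank-sum test between two
#' cross-type distance samples (e.g. PD1-high -> Ki-67+ versus FOXP3+ ->
#' Ki-67+), with a shared-break histogram summary for reporting.
#'
#' @param dist_a,dist_b Numeric distance vectors (um), or `nn_result`
#'   objects.
#' @param breaks Number of histogram bins over the pooled range.
#' @return A `rank_test` list with an extra `histogram` element (`breaks`,
#'   `counts_a`, `counts_b`).
#' @export
compare_nn <- function(dist_a, dist_b, breaks = 30) {
  if (inherits(dist_a, "nn_result")) dist_a <- dist_a$distances
  if (inherits(dist_b, "nn_result")) dist_b <- dist_b$distances
  out <- rank_sum_test(dist_a, dist_b, what = "nearest-neighbour distance")
  brk <- seq(0, max(dist_a, dist_b) * (1 + 1e-9), length.out = breaks + 1)
  out$histogram <- list(
    breaks = brk,
    counts_a = graphics::hist(dist_a, breaks = brk, plot = FALSE)$counts,
    counts_b = graphics::hist(dist_b, breaks = brk, plot = FALSE)$counts)
  out
}
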