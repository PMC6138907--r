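#' Default radius grid for Ripley's K
#'
#' 50 evenly spaced radii from 0 to one quarter of the shorter window side —
#' the upper limit beyond which edge correction for a rectangle becomes
#' unreliable.
#'
#' @param window A [tissue_window()].
#' @param n_radii Number of radii.
#' @return Numeric vector of radii (um), starting at 0.
#' @export
default_radii <- function(window, n_radii = 50) {
  seq(0, min(window_sides(window)) / 4, length.out = n_radii)
}

#' Ripley's K function of a point pattern
#'
#' Second-order summary of a phenotype's spatial distribution: `K(r)` is the
#' expected number of further cells within distance `r` of a typical cell,
#' divided by the intensity. Under complete spatial randomness (CSR)
#' `K(r) = pi r^2`; values above that indicate clustering. The estimator is
#'
#' `K_hat(r) = |A| / (n (n - 1)) * sum_{i != j} w_ij 1(d_ij <= r)`
#'
#' with `w_ij` the translation edge-correction weight
#' `|A| / ((a - |dx_ij|)(b - |dy_ij|))` for a rectangle with sides `a`, `b`
#' (exact for rectangular windows), or 1 when `correction = "none"`.
#'
#' @param points Data frame (or matrix) with `x`, `y` coordinates in um, all
#'   inside `window`; at least 2 points.
#' @param window A [tissue_window()].
#' @param radii Strictly increasing radius grid starting at >= 0; defaults to
#'   [default_radii()]. The largest radius may not exceed one quarter of the
#'   shorter window side.
#' @param correction `"translation"` (default) or `"none"`.
#' @return Object of class `kfun_result`: `r`, `k_obs`, `k_csr` (`pi r^2`),
#'   `n`, `correction`, `window` and the scalar `cluster_score` (see
#'   [cluster_score()]).
#' @examples
#' w <- tissue_window(0, 0, 1000, 1000)
#' pp <- simulate_csr(0.001, w, seed = 1)
#' k <- ripley_k(pp, w)
#' @export
ripley_k <- function(points, window, radii = NULL,
                     correction = c("translation", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(window, "tissue_window"))
  points <- as.data.frame(points)
  if (is.null(points$x) && ncol(points) >= 2) {
    names(points)[1:2] <- c("x", "y")
  }
  n <- nrow(points)
  if (n < 2) stop("Ripley's K needs at least 2 points", call. = FALSE)
  assert_points_in_window(points$x, points$y, window, "cells")
  if (is.null(radii)) radii <- default_radii(window)
  if (length(radii) < 2 || any(diff(radii) <= 0) || radii[1] < 0) {
    stop("radii must be a strictly increasing grid starting at >= 0",
         call. = FALSE)
  }
  guard <- min(window_sides(window)) / 4
  if (max(radii) > guard * (1 + 1e-9)) {
    stop(sprintf("largest radius %g exceeds the guard of %g um (1/4 of the shorter window side)",
                 max(radii), guard), call. = FALSE)
  }
  area <- window_area(window)
  sides <- window_sides(window)
  acc <- kfun_pair_weights(points$x, points$y, radii, sides[1], sides[2],
                           if (correction == "translation") 1L else 0L)
  k_obs <- area / (n * (n - 1)) * acc
  res <- structure(list(r = radii, k_obs = k_obs, k_csr = pi * radii^2,
                        n = n, correction = correction, window = window,
                        cluster_score = NA_real_),
                   class = "kfun_result")
  res$cluster_score <- cluster_score(res)
  res
}

#' @export
print.kfun_result <- function(x, ...) {
  cat(sprintf("Ripley's K: %d points, %s correction, r in [%g, %g] um\n",
              x$n, x$correction, min(x$r), max(x$r)))
  cat(sprintf("  cluster score %.3f (0 = CSR, > 0 = clustered)\n",
              x$cluster_score))
  invisible(x)
}

#' @export
plot.kfun_result <- function(x, ...) {
  graphics::plot(x$r, x$k_obs, type = "l",
                 xlab = "r (um)", ylab = "K(r) (um^2)", ...)
  graphics::lines(x$r, x$k_csr, lty = 2, col = 2)
  graphics::legend("topleft", legend = c("observed", "CSR"),
                   lty = c(1, 2), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Cluster score: normalized integrated K deviation
#'
#' Reduces the gap between the observed K curve and the CSR reference to one
#' scalar: the trapezoidal integral of `K_obs(r) - pi r^2` over the radius
#' grid, divided by the integral of `pi r^2` over the same grid. The
#' normalization makes the score dimensionless and window-scale-free:
#' 0 for a CSR-like pattern, positive for clustering (e.g. 1 when
#' `K_obs = 2 pi r^2` throughout), negative for regularity.
#'
#' @param x A `kfun_result`, or a numeric vector of observed K values (then
#'   supply `r`).
#' @param r Radius grid matching `x` when `x` is a plain vector.
#' @param ... Unused.
#' @return Dimensionless scalar.
#' @export
cluster_score <- function(x, ...) UseMethod("cluster_score")

#' @rdname cluster_score
#' @export
cluster_score.kfun_result <- function(x, ...) {
  cluster_score.default(x$k_obs, x$r)
}

#' @rdname cluster_score
#' @export
cluster_score.default <- function(x, r, ...) {
  if (length(x) != length(r)) {
    stop("K values and radius grid have different lengths", call. = FALSE)
  }
  if (length(r) < 2) stop("need at least 2 radii to integrate", call. = FALSE)
  trapz <- function(fx) sum(diff(r) * (fx[-1] + fx[-length(fx)]) / 2)
  ref <- trapz(pi * r^2)
  if (ref <= 0) stop("degenerate radius grid: reference integral is 0",
                     call. = FALSE)
  trapz(x - pi * r^2) / ref
}

#' Compare cluster scores between two phenotypes
#'
#' Two-sided Mann-Whitney rank-sum comparison of per-case cluster scores
#' (e.g. PD1-high vs FOXP3+ across a case series), as used to establish that
#' one phenotype is more clustered than another.
#'
#' @param scores_a,scores_b Numeric vectors of per-case cluster scores.
#' @return A `rank_test` list: group medians, test statistic and p-value.
#' @export
compare_cluster_scores <- function(scores_a, scores_b) {
  rank_sum_test(scores_a, scores_b, what = "cluster score")
}
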