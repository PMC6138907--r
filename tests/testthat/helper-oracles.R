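# Independent brute-force oracles used to cross-check the compiled
# implementations. Deliberately naive: full pairwise loops over small n.

# Ripley's K by direct evaluation of the estimator definition.
brute_force_k <- function(points, window, radii,
                          correction = c("none", "translation")) {
  correction <- match.arg(correction)
  n <- nrow(points)
  area <- window_area(window)
  a <- window$x_max - window$x_min
  b <- window$y_max - window$y_min
  k <- numeric(length(radii))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- points$x[i] - points$x[j]
      dy <- points$y[i] - points$y[j]
      d <- sqrt(dx^2 + dy^2)
      w <- if (correction == "translation") {
        (a * b) / ((a - abs(dx)) * (b - abs(dy)))
      } else 1
      k <- k + w * (d <= radii)
    }
  }
  area / (n * (n - 1)) * k
}

# Cross-type nearest neighbour by the full O(n * m) distance matrix.
brute_force_nn <- function(query, target) {
  vapply(seq_len(nrow(query)), function(i) {
    min(sqrt((query$x[i] - target$x)^2 + (query$y[i] - target$y)^2))
  }, numeric(1))
}

random_points <- function(n, window) {
  data.frame(x = runif(n, window$x_min, window$x_max),
             y = runif(n, window$y_min, window$y_max))
}

unit_km <- tissue_window(0, 0, 1000, 1000)

# One paired linked/independent bivariate draw under the co-localization
# scenario parameters, returning the per-class point sets. Both arms use the
# same seed, so the first class (and its cluster parents) is identical in the
# two arms and only the second class's linkage differs — the paired design.
draw_bivariate_pair <- function(seed, kappa = 5e-5, mu = 20, sigma = 20,
                                window = unit_km) {
  split_classes <- function(pat) {
    list(a = pat[pat$label == "PD1hi", c("x", "y")],
         b = pat[pat$label == "Ki67pos", c("x", "y")])
  }
  s <- derive_seed(seed, "pair")
  linked <- simulate_bivariate("linked", kappa, mu, mu, sigma, window,
                               seed = s)
  indep <- simulate_bivariate("independent", kappa, mu, mu, sigma, window,
                              seed = s)
  list(linked = split_classes(linked), independent = split_classes(indep))
}
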