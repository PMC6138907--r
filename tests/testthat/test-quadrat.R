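test_that("tessellation retains only complete quadrats and assigns half-open", {
  w <- tissue_window(0, 0, 400, 400)
  g <- tessellate(data.frame(x = 1, y = 1), data.frame(x = 399, y = 399),
                  w, 200)
  expect_equal(nrow(g), 4)
  # 100 um strip dropped; the cell at x = 450 is excluded from the counts
  w2 <- tissue_window(0, 0, 500, 400)
  g2 <- tessellate(data.frame(x = c(50, 450), y = c(50, 50)),
                   data.frame(x = numeric(0), y = numeric(0)), w2, 200)
  expect_equal(nrow(g2), 4)
  expect_equal(sum(g2$count_a), 1)
  expect_equal(attr(g2, "n_dropped_a"), 1)
  # a cell on a shared boundary is counted exactly once, in the upper quadrat
  g3 <- tessellate(data.frame(x = 200, y = 100),
                   data.frame(x = numeric(0), y = numeric(0)), w, 200)
  expect_equal(sum(g3$count_a), 1)
  expect_equal(g3$count_a[g3$col == 2 & g3$row == 1], 1)
  expect_error(tessellate(data.frame(x = 1, y = 1),
                          data.frame(x = 1, y = 1), w, 500), "exceeds")
})

test_that("quadrat counts conserve the cells of the retained region", {
  set.seed(12)
  for (i in 1:20) {
    w <- tissue_window(0, 0, runif(1, 300, 1200), runif(1, 300, 1200))
    side <- sample(c(100, 150, 200), 1)
    a <- random_points(sample(50:400, 1), w)
    b <- random_points(sample(50:400, 1), w)
    g <- tessellate(a, b, w, side)
    n_col <- max(g$col)
    n_row <- max(g$row)
    in_region <- function(p) sum(p$x < w$x_min + n_col * side &
                                 p$y < w$y_min + n_row * side)
    expect_equal(sum(g$count_a), in_region(a))
    expect_equal(sum(g$count_b), in_region(b))
  }
})

test_that("Morisita-Horn matches hand values and its algebraic properties", {
  expect_equal(morisita_horn(c(3, 1), c(1, 3)), 0.6)
  expect_equal(morisita_horn(c(2, 0, 1), c(4, 0, 2)), 1)
  expect_equal(morisita_horn(c(1, 0), c(0, 1)), 0)
  set.seed(44)
  for (i in 1:50) {
    x <- rpois(sample(3:30, 1), 5)
    y <- rpois(length(x), 5)
    if (sum(x) == 0 || sum(y) == 0) next
    mh <- morisita_horn(x, y)
    expect_gte(mh, 0)
    expect_lte(mh, 1 + 1e-12)
    expect_equal(mh, morisita_horn(y, x))
    expect_equal(mh, morisita_horn(3.7 * x, y))
  }
  expect_error(morisita_horn(1:3, 1:2), "lengths")
  expect_error(morisita_horn(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("Pearson on filtered quadrats honours the display filter", {
  expect_equal(pearson_counts(c(10, 20, 30), c(20, 40, 60)), 1)
  expect_equal(pearson_counts(c(10, 20, 30), c(30, 20, 10)), -1)
  # filter keeps quadrats 1 and 3 only -> fewer than 3 -> error
  expect_error(pearson_counts(c(6, 0, 12, 2), c(5, 1, 9, 3), min_cells = 5),
               "2 quadrat")
  expect_warning(p <- pearson_counts(c(10, 10, 10), c(1, 2, 3)), "constant")
  expect_true(is.na(p))
})

test_that("high-interaction fraction uses a strict cutoff over analysed quadrats", {
  grid51 <- list(count_a = rep(51, 8), count_b = rep(51, 8))
  expect_equal(high_interaction_fraction(grid51), 1)
  grid50 <- list(count_a = rep(50, 8), count_b = rep(50, 8))
  expect_equal(high_interaction_fraction(grid50), 0)
  mixed <- list(count_a = c(60, 60, 3), count_b = c(60, 10, 2))
  expect_equal(high_interaction_fraction(mixed), 0.5) # third quadrat filtered out
  expect_error(high_interaction_fraction(list(count_a = c(1, 0),
                                              count_b = c(0, 1))),
               "display filter")
})

test_that("multiscale interaction is deterministic and flags degenerate scales", {
  pair <- draw_bivariate_pair(2)
  ms1 <- multiscale_interaction(pair$linked$a, pair$linked$b, unit_km)
  ms2 <- multiscale_interaction(pair$linked$a, pair$linked$b, unit_km)
  expect_identical(ms1, ms2)
  expect_named(ms1, c("100", "200", "400"))
  one <- multiscale_interaction(pair$linked$a, pair$linked$b, unit_km,
                                sides = 1000)
  expect_true(is.na(one[["1000"]]$pearson)) # single quadrat: undefined
  expect_equal(one[["1000"]]$n_quadrats_total, 1)
})

test_that("tessellated CSR pairs agree with the direct Poisson-count oracle for MH", {
  # Counts of a CSR pattern over s x s quadrats are i.i.d. Poisson(lambda s^2);
  # the oracle samples that distribution directly.
  lambda <- 0.001
  side <- 200
  n_quad <- 25
  mu <- lambda * side^2
  set.seed(77)
  oracle <- mean(replicate(1e5, {
    morisita_horn(rpois(n_quad, mu) + 0L, rpois(n_quad, mu))
  }))
  sim <- mean(replicate(200, {
    g <- tessellate(simulate_csr(lambda, unit_km),
                    simulate_csr(lambda, unit_km), unit_km, side)
    morisita_horn(g$count_a, g$count_b)
  }))
  expect_lt(abs(sim - oracle), 0.1)
})
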