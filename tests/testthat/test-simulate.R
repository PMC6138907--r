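test_that("degenerate windows and non-positive rates are rejected", {
  expect_error(tissue_window(0, 0, 0, 10), "degenerate")
  expect_error(tissue_window(5, 0, 1, 10), "degenerate")
  expect_equal(window_area(tissue_window(0, 0, 1000, 500)), 5e5)
  expect_error(simulate_csr(0, unit_km), "positive")
  expect_error(simulate_csr(-1, unit_km), "positive")
  expect_error(simulate_thomas(5e-5, 50, 0, unit_km), "positive")
})

test_that("CSR counts have Poisson mean and variance", {
  set.seed(42)
  counts <- replicate(500, nrow(simulate_csr(0.001, unit_km)))
  expected <- 0.001 * window_area(unit_km)
  # mean: SE = sqrt(lambda |A| / n)
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 500))
  # variance equals the mean; SE of the sample variance of a Poisson is
  # approximately sqrt((lambda + 2 lambda^2) / n)
  se_var <- sqrt((expected + 2 * expected^2) / 500)
  expect_lt(abs(var(counts) - expected), 3 * se_var)
})

test_that("generators are deterministic under a fixed seed and stay in-window", {
  for (gen in list(function(s) simulate_csr(0.001, unit_km, seed = s),
                   function(s) simulate_thomas(5e-5, 50, 20, unit_km, seed = s),
                   function(s) simulate_bivariate("linked", 5e-5, 20, 20, 20,
                                                  unit_km, seed = s))) {
    p1 <- gen(7)
    p2 <- gen(7)
    expect_identical(p1, p2)
    expect_true(all(p1$x >= 0 & p1$x <= 1000 & p1$y >= 0 & p1$y <= 1000))
    expect_false(identical(p1, gen(8)))
  }
})

test_that("Thomas retained count matches the Neyman-Scott expectation", {
  set.seed(99)
  counts <- replicate(100, nrow(simulate_thomas(5e-5, 50, 20, unit_km)))
  expected <- 5e-5 * window_area(unit_km) * 50 # parent buffer removes edge loss
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(100))
})

test_that("window-scale dispersion dissolves clusters towards CSR", {
  expect_warning(simulate_thomas(5e-5, 50, 600, unit_km), "resolvable")
  set.seed(5)
  scores <- replicate(5, {
    p <- simulate_thomas(1e-4, 25, 500, unit_km)
    ripley_k(p, unit_km)$cluster_score
  })
  expect_lt(abs(mean(scores)), 0.15)
})

test_that("linked parents force co-location relative to independent draws", {
  nn_wins <- 0
  mh_wins <- 0
  n_pairs <- 25
  for (s in seq_len(n_pairs)) {
    pair <- draw_bivariate_pair(s)
    nn_l <- cross_nn_distances(pair$linked$a, pair$linked$b)$median
    nn_i <- cross_nn_distances(pair$independent$a, pair$independent$b)$median
    if (nn_l < nn_i) nn_wins <- nn_wins + 1
    gl <- tessellate(pair$linked$a, pair$linked$b, unit_km, 200)
    gi <- tessellate(pair$independent$a, pair$independent$b, unit_km, 200)
    mh_l <- morisita_horn(gl$count_a, gl$count_b)
    if (mh_l > morisita_horn(gi$count_a, gi$count_b)) mh_wins <- mh_wins + 1
  }
  expect_gte(nn_wins, round(0.9 * n_pairs))
  expect_gte(mh_wins, round(0.9 * n_pairs))
})

test_that("a zero-offspring class yields an empty point set that downstream stages reject", {
  pat <- simulate_bivariate("linked", 5e-5, 20, 0, 20, unit_km, seed = 3)
  b <- pat[pat$label == "Ki67pos", ]
  expect_equal(nrow(b), 0)
  expect_error(cross_nn_distances(pat[pat$label == "PD1hi", ], b),
               "empty target")
  expect_error(morisita_horn(c(1, 2), c(0, 0)), "zero total")
})

test_that("intensity attachment is seeded, label-preserving and model-checked", {
  pat <- simulate_thomas(5e-5, 20, 20, unit_km, seed = 4, label = "Tfh")
  t1 <- attach_intensities(pat, seed = 11)
  t2 <- attach_intensities(pat, seed = 11)
  expect_identical(t1, t2)
  expect_identical(t1$true_label, pat$label)
  expect_true(all(t1$CD4 > 0 & t1$PD1 > 0))
  expect_error(attach_intensities(pat, models = list(Treg = list())),
               "no intensity model")
  expect_error(
    attach_intensities(pat, models = list(Tfh = list(CD4 = c(4, 0.25)))),
    "lacks a model")
})

test_that("identical intensity models make two classes indistinguishable", {
  same <- list(A = list(M = c(3, 0.25)), B = list(M = c(3, 0.25)))
  pat <- rbind(simulate_csr(5e-4, unit_km, seed = 1, label = "A"),
               simulate_csr(5e-4, unit_km, seed = 2, label = "B"))
  tab <- attach_intensities(pat, models = same, channels = "M", seed = 9)
  # threshold at the pooled median classifies at chance
  thr <- median(tab$M)
  acc <- mean((tab$M >= thr) == (tab$true_label == "A"))
  expect_lt(abs(acc - 0.5), 0.05)
})

test_that("seed substreams are stable and within the 32-bit range", {
  expect_identical(derive_seed(1, "tfh"), derive_seed(1, "tfh"))
  expect_false(derive_seed(1, "tfh") == derive_seed(1, "treg"))
  expect_false(derive_seed(1, "tfh") == derive_seed(2, "tfh"))
  s <- vapply(1:50, function(i) derive_seed(i, "case"), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
})
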