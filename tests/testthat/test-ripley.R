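test_that("the uncorrected estimator reproduces the hand-evaluated two-point case", {
  w <- tissue_window(0, 0, 100, 100)
  pts <- data.frame(x = c(0, 3), y = c(0, 4))
  k <- ripley_k(pts, w, radii = c(0, 4.99, 10), correction = "none")
  expect_equal(k$k_obs, c(0, 0, 10000))
  expect_equal(k$k_csr, pi * c(0, 4.99, 10)^2)
  expect_equal(k$k_obs[1], 0) # no pairs at r = 0 for distinct points
})

test_that("preconditions guard point count and the radius range", {
  w <- tissue_window(0, 0, 100, 100)
  expect_error(ripley_k(data.frame(x = 1, y = 1), w), "at least 2")
  expect_error(ripley_k(data.frame(x = c(1, 2), y = c(1, 2)), w,
                        radii = c(0, 30)), "guard")
  expect_error(ripley_k(data.frame(x = c(1, 200), y = c(1, 2)), w),
               "outside the window")
  expect_error(ripley_k(data.frame(x = c(1, 2), y = c(1, 2)), w,
                        radii = c(5, 5, 6)), "strictly increasing")
})

test_that("compiled pair counting matches the brute-force oracle on random instances", {
  set.seed(31)
  w <- tissue_window(0, 0, 400, 300)
  radii <- seq(0, 75, length.out = 20)
  for (i in 1:100) {
    pts <- random_points(sample(2:200, 1), w)
    k <- ripley_k(pts, w, radii, correction = "none")
    expect_equal(k$k_obs, brute_force_k(pts, w, radii, "none"))
  }
  # translation weights against the same oracle on a smaller batch
  for (i in 1:20) {
    pts <- random_points(sample(2:100, 1), w)
    k <- ripley_k(pts, w, radii, correction = "translation")
    expect_equal(k$k_obs, brute_force_k(pts, w, radii, "translation"))
  }
})

test_that("K is invariant under translation and quarter-turn rotation", {
  set.seed(8)
  w <- tissue_window(0, 0, 600, 400)
  pts <- random_points(150, w)
  k0 <- ripley_k(pts, w, seq(0, 100, length.out = 25))
  shifted <- data.frame(x = pts$x + 1000, y = pts$y - 50)
  ws <- tissue_window(1000, -50, 1600, 350)
  expect_equal(ripley_k(shifted, ws, seq(0, 100, length.out = 25))$k_obs,
               k0$k_obs)
  rotated <- data.frame(x = pts$y, y = 600 - pts$x)
  wr <- tissue_window(0, 0, 400, 600)
  expect_equal(ripley_k(rotated, wr, seq(0, 100, length.out = 25))$k_obs,
               k0$k_obs)
  expect_true(all(diff(k0$k_obs) >= 0)) # K is a cumulative quantity
})

test_that("the cluster score is the normalized integrated K deviation", {
  r <- seq(0, 100, length.out = 30)
  expect_equal(cluster_score(pi * r^2, r), 0)
  expect_equal(cluster_score(2 * pi * r^2, r), 1)
  expect_equal(cluster_score(0.5 * pi * r^2, r), -0.5)
  expect_error(cluster_score(pi * r^2, r[-1]), "different lengths")
  expect_error(cluster_score(1, 1), "at least 2")
})

test_that("Thomas patterns score positive and above paired CSR patterns", {
  wins <- 0
  for (s in 1:20) {
    th <- simulate_thomas(5e-5, 50, 20, unit_km,
                          seed = derive_seed(s, "thomas"))
    cs <- simulate_csr(2.5e-3, unit_km, seed = derive_seed(s, "csr"))
    ts <- ripley_k(th, unit_km)$cluster_score
    expect_gt(ts, 0)
    if (ts > ripley_k(cs, unit_km)$cluster_score) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("cluster-score comparison handles identity and complete separation", {
  x <- c(0.1, 0.5, 0.9, 1.4, 2.2)
  same <- compare_cluster_scores(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$median_a, same$median_b)
  apart <- compare_cluster_scores(seq(2, 3, length.out = 15),
                                  seq(0, 1, length.out = 15))
  expect_lt(apart$p_value, 0.001)
  expect_gt(apart$median_a, apart$median_b)
  expect_error(compare_cluster_scores(numeric(0), 1), "non-empty")
})
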