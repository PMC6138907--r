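# Explicit thresholds used throughout so the rule table is tested in
# isolation from threshold estimation.
cfg <- gating_config(cd4 = 10, foxp3 = 10, ki67 = 10, pd1_high = 100)

cell_row <- function(cd4, pd1, foxp3, ki67, id = 1) {
  data.frame(cell_id = id, x = 0, y = 0, CD4 = cd4, PD1 = pd1,
             FOXP3 = foxp3, Ki67 = ki67)
}

test_that("PD1 calibration takes the reference quantile and leaves the config untouched", {
  ref <- data.frame(PD1 = 1:100)
  base <- gating_config(q_ref = 0.05)
  out <- calibrate_pd1_threshold(ref, base)
  # type-7 quantile: 1 + 0.05 * 99
  expect_equal(out$pd1_high, 5.95)
  expect_null(base$pd1_high)
  near_min <- calibrate_pd1_threshold(ref, gating_config(q_ref = 1e-9))
  expect_equal(near_min$pd1_high, 1, tolerance = 1e-6)
  single <- calibrate_pd1_threshold(data.frame(PD1 = rep(7, 5)),
                                    gating_config(q_ref = 0.6))
  expect_equal(single$pd1_high, 7)
  expect_error(calibrate_pd1_threshold(data.frame(PD1 = numeric(0))),
               "non-empty")
  expect_error(calibrate_pd1_threshold(data.frame(x = 1)), "PD1")
  expect_error(calibrate_pd1_threshold(data.frame(PD1 = c(0, 0))), "zero")
  expect_error(gating_config(q_ref = 0), "q_ref")
  expect_error(gating_config(cd4 = -1), "positive")
})

test_that("the subset rule table matches the marker definitions", {
  calls <- gate_cells(rbind(
    cell_row(50, 101, 5, 5, 1),    # CD4+ PD1hi FOXP3-  -> Tfh
    cell_row(50, 100, 50, 5, 2),   # boundary PD1 counts as high -> Tfr
    cell_row(50, 99, 50, 5, 3),    # CD4+ PD1lo FOXP3+  -> Treg
    cell_row(50, 99, 5, 50, 4),    # CD4+ only          -> other, Ki67+
    cell_row(5, 101, 5, 5, 5),     # CD4- PD1hi         -> other, pd1_hi flag
    cell_row(0, 0, 0, 0, 6)), cfg) # all zero           -> other, no flags
  expect_equal(calls$phenotype,
               c("Tfh", "Tfr", "Treg", "other", "other", "other"))
  expect_equal(calls$ki67_pos, c(F, F, F, T, F, F))
  expect_equal(calls$pd1_hi, c(T, T, F, F, T, F))
  expect_false(any(unlist(calls[6, c("cd4_pos", "pd1_hi", "foxp3_pos",
                                     "ki67_pos")])))
  expect_error(gate_cells(cell_row(1, 1, 1, 1)[, -4], cfg), "CD4")
})

test_that("gating is pure, exhaustive, mutually exclusive and monotone in the PD1 threshold", {
  set.seed(21)
  cells <- data.frame(cell_id = 1:500, x = 0, y = 0,
                      CD4 = rlnorm(500, 2, 1.5), PD1 = rlnorm(500, 2, 1.5),
                      FOXP3 = rlnorm(500, 2, 1.5), Ki67 = rlnorm(500, 2, 1.5))
  calls <- gate_cells(cells, cfg)
  expect_identical(calls, gate_cells(cells, cfg))
  expect_true(all(calls$phenotype %in% c("Tfh", "Tfr", "Treg", "other")))
  # phenotype is the unique consequence of the flags
  expected <- ifelse(calls$cd4_pos & calls$pd1_hi & !calls$foxp3_pos, "Tfh",
              ifelse(calls$cd4_pos & calls$pd1_hi & calls$foxp3_pos, "Tfr",
              ifelse(calls$cd4_pos & !calls$pd1_hi & calls$foxp3_pos, "Treg",
                     "other")))
  expect_identical(calls$phenotype, expected)
  n_hi <- vapply(c(5, 20, 100, 400), function(tau) {
    sum(gate_cells(cells, gating_config(cd4 = 10, foxp3 = 10, ki67 = 10,
                                        pd1_high = tau))$pd1_hi)
  }, numeric(1))
  expect_true(all(diff(n_hi) <= 0))
})

test_that("subset summaries report fractions, sentinels and undefined denominators", {
  calls <- gate_cells(rbind(
    do.call(rbind, lapply(1:10, function(i) cell_row(50, 101, 5, 5, i))),
    do.call(rbind, lapply(11:15, function(i) cell_row(50, 5, 50, 5, i))),
    cell_row(50, 101, 50, 5, 16),
    do.call(rbind, lapply(17:100, function(i) cell_row(50, 5, 5, 5, i)))),
    cfg)
  s <- subset_summary(calls)
  expect_equal(s$n_cd4, 100)
  expect_equal(unname(s$counts[c("Tfh", "Treg", "Tfr")]), c(10, 5, 1))
  expect_equal(s$subset_fraction, 0.16)
  expect_equal(s$tfr_fraction_of_pd1hi, 1 / 11)
  no_cd4 <- subset_summary(gate_cells(cell_row(1, 1, 1, 1), cfg))
  expect_true(is.na(no_cd4$subset_fraction))
  only_pd1 <- subset_summary(gate_cells(cell_row(5, 101, 5, 5), cfg))
  expect_identical(only_pd1$pd1hi_foxp3_ratio, Inf)
})

test_that("surrogate regression recovers identity and rejects degenerate designs", {
  make_case <- function(n_tfh, n_other) {
    gate_cells(rbind(
      do.call(rbind, lapply(seq_len(n_tfh), function(i)
        cell_row(50, 101, 5, 5, i))),
      do.call(rbind, lapply(seq_len(n_other), function(i)
        cell_row(50, 5, 5, 5, n_tfh + i)))), cfg)
  }
  # PD1hi count equals Tfh count in every case (no CD4- PD1hi cells)
  cases <- list(a = make_case(5, 10), b = make_case(9, 10),
                c = make_case(14, 10), d = make_case(2, 10))
  # no Treg/FOXP3+ cells anywhere: that pair is flagged degenerate
  expect_warning(surrogate_agreement(cases), "constant")
  rep <- suppressWarnings(surrogate_agreement(cases))
  expect_equal(rep$r_squared[rep$subset == "Tfh"], 1)
  expect_equal(rep$slope[rep$subset == "Tfh"], 1)
  expect_true(rep$degenerate[rep$subset == "Treg"])
  expect_true(is.na(rep$r_squared[rep$subset == "Treg"]))
  expect_error(surrogate_agreement(cases[1:2]), "at least 3")
})

test_that("bimodality-split thresholds recover generating labels exactly on separated models", {
  cells <- simulate_full_tissue(17)
  calls <- gate_cells(cells, gating_config())
  recovered <- ifelse(calls$ki67_pos, "Ki67pos", calls$phenotype)
  expect_identical(recovered, cells$true_label)
  expect_error(estimate_positivity_threshold(rlnorm(500, 3, 0.3)),
               "not bimodal")
})
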