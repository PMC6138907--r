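#' Gating configuration
#'
#' Holds the per-marker positivity thresholds and the PD1-high threshold used
#' to call T-cell subsets. Thresholds left `NULL` are estimated from the data
#' at gating time by a bimodality split ([estimate_positivity_threshold()]);
#' the PD1-high threshold is normally set by [calibrate_pd1_threshold()]
#' from a reference population rather than supplied directly.
#'
#' @param cd4,foxp3,ki67 Positivity thresholds (intensity units) or `NULL`.
#' @param pd1_high PD1-high threshold (intensity units) or `NULL`.
#' @param q_ref Reference quantile used for PD1 calibration, in (0, 1).
#'   The default 0.05 sets the threshold at the 5th percentile of the
#'   reference PD1 distribution, so nearly all reference cells count as
#'   PD1-high.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(cd4 = NULL, foxp3 = NULL, ki67 = NULL,
                          pd1_high = NULL, q_ref = 0.05) {
  if (!is.numeric(q_ref) || length(q_ref) != 1 || q_ref <= 0 || q_ref >= 1) {
    stop("q_ref must be a single number in (0, 1)", call. = FALSE)
  }
  for (thr in list(cd4 = cd4, foxp3 = foxp3, ki67 = ki67, pd1_high = pd1_high)) {
    if (!is.null(thr) && (!is.finite(thr) || thr <= 0)) {
      stop("thresholds must be positive when supplied", call. = FALSE)
    }
  }
  structure(list(cd4 = cd4, foxp3 = foxp3, ki67 = ki67,
                 pd1_high = pd1_high, q_ref = q_ref),
            class = "gating_config")
}

#' @export
print.gating_config <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "<estimate from data>" else format(v)
  cat("gating configuration\n")
  cat("  CD4 positivity:  ", fmt(x$cd4), "\n")
  cat("  FOXP3 positivity:", fmt(x$foxp3), "\n")
  cat("  Ki67 positivity: ", fmt(x$ki67), "\n")
  cat("  PD1-high:        ",
      if (is.null(x$pd1_high)) "<calibrate from reference>" else format(x$pd1_high),
      sprintf("(q_ref = %g)", x$q_ref), "\n")
  invisible(x)
}

#' Calibrate the PD1-high threshold from a reference population
#'
#' The threshold separating PD1-high from PD1-low cells is anchored on a
#' reference population of cells known to be PD1-high (tonsillar
#' germinal-centre Tfh cells in the original study): it is set to the
#' `q_ref` quantile of the reference PD1 intensities, so that a fraction
#' `1 - q_ref` of reference cells fall above it. Quantiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#'
#' @param reference A cell table with a `PD1` intensity column.
#' @param config A [gating_config()]; its `q_ref` is used and its `pd1_high`
#'   replaced. The input object is not modified.
#' @return A new `gating_config` with `pd1_high` set.
#' @export
calibrate_pd1_threshold <- function(reference, config = gating_config()) {
  stopifnot(inherits(config, "gating_config"))
  if (is.null(reference$PD1) || nrow(reference) == 0) {
    stop("calibration requires a non-empty reference with a PD1 channel",
         call. = FALSE)
  }
  pd1 <- reference$PD1
  if (all(pd1 == 0)) {
    stop("reference PD1 channel is all zero; cannot calibrate", call. = FALSE)
  }
  config$pd1_high <- unname(stats::quantile(pd1, config$q_ref, type = 7))
  config
}

#' Positivity threshold from a bimodality split
#'
#' Default positivity criterion for a marker channel when no explicit
#' threshold is configured: a Gaussian kernel density estimate of the
#' log-intensities is computed, its local maxima located, and the threshold
#' placed midway (on the log scale) between the two highest modes. The log
#' scale suits the right-skewed, strictly positive intensities typical of
#' immunohistochemical staining.
#'
#' @param intensities Positive intensity values.
#' @return Threshold on the intensity scale.
#' @export
estimate_positivity_threshold <- function(intensities) {
  v <- intensities[is.finite(intensities) & intensities > 0]
  if (length(v) < 10) {
    stop("too few positive intensities to estimate a threshold", call. = FALSE)
  }
  d <- stats::density(log(v))
  y <- d$y
  k <- length(y)
  is_peak <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
               FALSE)
  peaks <- which(is_peak)[order(y[which(is_peak)], decreasing = TRUE)]
  if (length(peaks) < 2) {
    stop("channel is not bimodal; supply an explicit threshold", call. = FALSE)
  }
  # second mode must be a genuine mode, not KDE jitter on the main one: the
  # density must dip below half the candidate's height between the two
  main <- peaks[1]
  second <- NA_integer_
  for (p in peaks[-1]) {
    valley <- min(y[seq(min(main, p), max(main, p))])
    if (valley < 0.5 * y[p]) {
      second <- p
      break
    }
  }
  if (is.na(second)) {
    stop("channel is not bimodal; supply an explicit threshold", call. = FALSE)
  }
  exp(mean(d$x[c(main, second)]))
}

resolve_thresholds <- function(cells, config) {
  est <- function(thr, channel) {
    if (!is.null(thr)) thr else estimate_positivity_threshold(cells[[channel]])
  }
  list(cd4 = est(config$cd4, "CD4"),
       foxp3 = est(config$foxp3, "FOXP3"),
       ki67 = est(config$ki67, "Ki67"),
       pd1_high = est(config$pd1_high, "PD1"))
}

#' Gate cells into T-cell subsets
#'
#' Applies the subset decision rules to per-cell marker intensities. A cell
#' at or above a threshold is positive (boundary cells are positive); below
#' is negative. The rule table is exhaustive and mutually exclusive:
#'
#' * CD4+, PD1 >= pd1_high, FOXP3-  -> `Tfh`
#' * CD4+, PD1 >= pd1_high, FOXP3+  -> `Tfr`
#' * CD4+, PD1 <  pd1_high, FOXP3+  -> `Treg`
#' * anything else                  -> `other`
#'
#' Independently of the subset call, single-marker flags are emitted:
#' `pd1_hi` (PD1 >= pd1_high regardless of CD4/FOXP3) and `foxp3_pos`, the
#' surrogate phenotypes used when only one marker is available, plus
#' `cd4_pos` and `ki67_pos`.
#'
#' @param cells Cell table with `cell_id`, `x`, `y` and intensity columns
#'   `CD4`, `PD1`, `FOXP3`, `Ki67`.
#' @param config A [gating_config()]. Positivity thresholds left `NULL` are
#'   estimated per channel by [estimate_positivity_threshold()]; that
#'   includes `pd1_high` when no reference population is available for
#'   [calibrate_pd1_threshold()] — the bimodality split then lands between
#'   the PD1-low and PD1-high modes.
#' @return Data frame of phenotype calls: `cell_id`, `x`, `y`, `phenotype`,
#'   `cd4_pos`, `pd1_hi`, `foxp3_pos`, `ki67_pos`; thresholds used are
#'   attached as attribute `thresholds`.
#' @export
gate_cells <- function(cells, config) {
  stopifnot(inherits(config, "gating_config"))
  needed <- c("CD4", "PD1", "FOXP3", "Ki67")
  missing_ch <- setdiff(needed, names(cells))
  if (length(missing_ch)) {
    stop(sprintf("cell table lacks channel(s): %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  thr <- resolve_thresholds(cells, config)
  cd4_pos <- cells$CD4 >= thr$cd4
  pd1_hi <- cells$PD1 >= thr$pd1_high
  foxp3_pos <- cells$FOXP3 >= thr$foxp3
  ki67_pos <- cells$Ki67 >= thr$ki67
  phenotype <- rep("other", nrow(cells))
  phenotype[cd4_pos & pd1_hi & !foxp3_pos] <- "Tfh"
  phenotype[cd4_pos & pd1_hi & foxp3_pos] <- "Tfr"
  phenotype[cd4_pos & !pd1_hi & foxp3_pos] <- "Treg"
  out <- data.frame(cell_id = cells$cell_id, x = cells$x, y = cells$y,
                    phenotype = phenotype, cd4_pos = cd4_pos,
                    pd1_hi = pd1_hi, foxp3_pos = foxp3_pos,
                    ki67_pos = ki67_pos)
  attr(out, "thresholds") <- thr
  out
}

#' Summarize gated subsets
#'
#' Per-phenotype counts and the summaries reported per case: subset
#' fractions of total CD4+ cells, the combined Tfh + Treg + Tfr fraction,
#' Tfr as a fraction of CD4+PD1-high cells, and the PD1hi:FOXP3+ ratio of
#' the surrogate counts. Fractions are `NA` (undefined) when the denominator
#' is zero; the ratio is `Inf` when there are PD1-high but no FOXP3+ cells.
#'
#' @param calls Phenotype calls from [gate_cells()].
#' @return A list of class `subset_summary`.
#' @export
subset_summary <- function(calls) {
  if (nrow(calls) == 0) stop("no phenotype calls to summarize", call. = FALSE)
  phenos <- c("Tfh", "Treg", "Tfr", "other")
  counts <- vapply(phenos, function(p) sum(calls$phenotype == p), integer(1))
  n_cd4 <- sum(calls$cd4_pos)
  n_pd1hi <- sum(calls$pd1_hi)
  n_foxp3 <- sum(calls$foxp3_pos)
  n_cd4_pd1hi <- sum(calls$cd4_pos & calls$pd1_hi)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    counts = counts,
    n_cells = nrow(calls),
    n_cd4 = n_cd4,
    n_pd1hi = n_pd1hi,
    n_foxp3 = n_foxp3,
    n_ki67 = sum(calls$ki67_pos),
    fraction_of_cd4 = vapply(counts[c("Tfh", "Treg", "Tfr")], frac,
                             numeric(1), den = n_cd4),
    subset_fraction = frac(sum(counts[c("Tfh", "Treg", "Tfr")]), n_cd4),
    tfr_fraction_of_pd1hi = frac(counts[["Tfr"]], n_cd4_pd1hi),
    pd1hi_foxp3_ratio = if (n_foxp3 > 0) n_pd1hi / n_foxp3
                        else if (n_pd1hi > 0) Inf else NA_real_
  ), class = "subset_summary")
}

#' @export
print.subset_summary <- function(x, ...) {
  cat(sprintf("%d cells gated; %d CD4+ (%d PD1hi, %d FOXP3+, %d Ki67+)\n",
              x$n_cells, x$n_cd4, x$n_pd1hi, x$n_foxp3, x$n_ki67))
  for (p in names(x$counts)) cat(sprintf("  %-6s %6d\n", p, x$counts[[p]]))
  if (is.finite(x$subset_fraction)) {
    cat(sprintf("  Tfh+Treg+Tfr = %.1f%% of CD4+\n", 100 * x$subset_fraction))
  }
  cat(sprintf("  PD1hi:FOXP3+ ratio = %s\n", format(x$pd1hi_foxp3_ratio,
                                                    digits = 3)))
  invisible(x)
}

#' Surrogate-marker agreement across cases
#'
#' Ordinary least-squares regression of the multi-marker subset count on the
#' single-marker surrogate count across cases (Tfh on PD1-high, Treg on
#' FOXP3+), validating the use of a single marker as a subset surrogate.
#'
#' @param calls_by_case Named list of phenotype-call data frames, one per
#'   case; at least three cases.
#' @return A data frame with one row per subset/surrogate pair: counts used,
#'   `r_squared`, `slope`, `p_value`, and a `degenerate` flag set (with a
#'   warning, and `NA` statistics) when the surrogate count is constant
#'   across cases.
#' @export
surrogate_agreement <- function(calls_by_case) {
  if (length(calls_by_case) < 3) {
    stop("surrogate regression needs at least 3 cases", call. = FALSE)
  }
  pairs <- list(c(subset = "Tfh", flag = "pd1_hi"),
                c(subset = "Treg", flag = "foxp3_pos"))
  rows <- lapply(pairs, function(p) {
    subset_n <- vapply(calls_by_case,
                       function(cl) sum(cl$phenotype == p[["subset"]]),
                       numeric(1))
    surrogate_n <- vapply(calls_by_case,
                          function(cl) sum(cl[[p[["flag"]]]]), numeric(1))
    if (stats::var(surrogate_n) == 0) {
      warning(sprintf("surrogate count for %s is constant across cases; R^2 undefined",
                      p[["subset"]]), call. = FALSE)
      return(data.frame(subset = p[["subset"]], surrogate = p[["flag"]],
                        n_cases = length(calls_by_case),
                        r_squared = NA_real_, slope = NA_real_,
                        p_value = NA_real_, degenerate = TRUE))
    }
    fit <- stats::lm(subset_n ~ surrogate_n)
    # summary warns on an exact fit (R^2 = 1), a legitimate outcome here
    sm <- suppressWarnings(summary(fit))
    data.frame(subset = p[["subset"]], surrogate = p[["flag"]],
               n_cases = length(calls_by_case),
               r_squared = sm$r.squared,
               slope = unname(stats::coef(fit)[2]),
               p_value = sm$coefficients[2, 4],
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}
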