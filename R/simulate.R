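#' Derive a reproducible sub-stream seed
#'
#' Expands one global seed into per-stage seeds so that adding a pipeline
#' stage does not perturb the draws of earlier stages. The derivation is a
#' fixed integer hash of the seed and a stage label; results stay within the
#' 32-bit signed range accepted by [set.seed()].
#'
#' @param seed Integer global seed.
#' @param label Character stage label (e.g. `"tfh"`, `"case3/intensities"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(label))
  m <- 2147483647 # 2^31 - 1
  h <- (abs(as.numeric(seed)) %% m)
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

new_pattern <- function(x, y, label, parent_id = NA_integer_) {
  data.frame(x = as.numeric(x), y = as.numeric(y),
             label = rep_len(label, length(x)),
             parent_id = rep_len(parent_id, length(x)))
}

#' Simulate complete spatial randomness (CSR)
#'
#' Homogeneous Poisson point process on a rectangular window: the null model
#' against which clustering of a cell phenotype is scored. The point count is
#' Poisson with mean `lambda * area`; coordinates are i.i.d. uniform.
#'
#' @param lambda Intensity in cells per square micrometre (> 0).
#' @param window A [tissue_window()].
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @param label Phenotype tag attached to every point.
#' @return A data frame with columns `x`, `y`, `label`, `parent_id`
#'   (`parent_id` is `NA` for Poisson points).
#' @examples
#' pp <- simulate_csr(0.001, tissue_window(0, 0, 1000, 1000), seed = 1)
#' @export
simulate_csr <- function(lambda, window, seed = NULL, label = "CSR") {
  stopifnot(inherits(window, "tissue_window"))
  if (!is.finite(lambda) || lambda <= 0) {
    stop("lambda must be a positive intensity (cells/um^2)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, lambda * window_area(window))
  new_pattern(stats::runif(n, window$x_min, window$x_max),
              stats::runif(n, window$y_min, window$y_max),
              label)
}

# Offspring of given parents: Poisson(mu) children each, isotropic
# Gaussian(sigma) displacement, clipped to the window. Parent ids index the
# supplied parent table.
thomas_offspring <- function(parents, mu, sigma, window, label) {
  n_off <- stats::rpois(nrow(parents), mu)
  total <- sum(n_off)
  if (total == 0) return(new_pattern(numeric(0), numeric(0), label))
  pid <- rep.int(seq_len(nrow(parents)), n_off)
  x <- parents$x[pid] + stats::rnorm(total, sd = sigma)
  y <- parents$y[pid] + stats::rnorm(total, sd = sigma)
  keep <- points_in_window(x, y, window)
  new_pattern(x[keep], y[keep], label, pid[keep])
}

thomas_parents <- function(kappa, window, buffer) {
  wb <- tissue_window(window$x_min - buffer, window$y_min - buffer,
                      window$x_max + buffer, window$y_max + buffer)
  n <- stats::rpois(1, kappa * window_area(wb))
  data.frame(x = stats::runif(n, wb$x_min, wb$x_max),
             y = stats::runif(n, wb$y_min, wb$y_max))
}

check_thomas_params <- function(kappa, mu, sigma, window) {
  if (!all(is.finite(c(kappa, mu, sigma))) || kappa <= 0 || mu <= 0 ||
      sigma <= 0) {
    stop("kappa, mu and sigma must all be positive", call. = FALSE)
  }
  if (sigma > min(window_sides(window)) / 2) {
    warning("cluster sd sigma exceeds half the shorter window side; ",
            "cluster structure will not be resolvable", call. = FALSE)
  }
}

#' Simulate a Thomas (Neyman-Scott) cluster process
#'
#' Emulates an inhomogeneously clustered phenotype such as the PD1-high
#' T-cell population: cluster parents are Poisson with intensity `kappa`,
#' each parent emits a Poisson(`mu`) number of offspring displaced by an
#' isotropic Gaussian with standard deviation `sigma`. Parents are simulated
#' on the window expanded by `4 * sigma` per side so clusters near the
#' boundary are not edge-thinned; offspring falling outside the window are
#' discarded. Expected retained count is approximately
#' `kappa * area * mu`.
#'
#' @param kappa Parent intensity, parents per square micrometre.
#' @param mu Mean offspring per parent.
#' @param sigma Cluster dispersion (um).
#' @inheritParams simulate_csr
#' @return A data frame with columns `x`, `y`, `label`, `parent_id`.
#' @export
simulate_thomas <- function(kappa, mu, sigma, window, seed = NULL,
                            label = "clustered") {
  stopifnot(inherits(window, "tissue_window"))
  check_thomas_params(kappa, mu, sigma, window)
  if (!is.null(seed)) set.seed(seed)
  parents <- thomas_parents(kappa, window, buffer = 4 * sigma)
  thomas_offspring(parents, mu, sigma, window, label)
}

#' Simulate a bivariate (two-phenotype) pattern
#'
#' Two labelled point classes with controlled spatial linkage. In the
#' `"linked"` variant both classes are Thomas processes sharing the same
#' cluster parents, forcing co-location (the situation of proliferating
#' Ki-67+ B-cell foci attended by PD1-high T-cells); in the `"independent"`
#' variant each class has its own, independently drawn, parent set.
#'
#' @param kind `"linked"` or `"independent"`.
#' @param kappa Parent intensity (parents/um^2).
#' @param mu_a,mu_b Mean offspring per parent for the two classes. A zero
#'   `mu_b` is allowed and yields an empty second class.
#' @param sigma Cluster dispersion (um), shared by both classes.
#' @param labels Length-2 character vector of phenotype tags.
#' @inheritParams simulate_csr
#' @return A data frame with columns `x`, `y`, `label`, `parent_id`; rows of
#'   both classes, class given by `label`.
#' @export
simulate_bivariate <- function(kind = c("linked", "independent"),
                               kappa, mu_a, mu_b, sigma, window,
                               seed = NULL, labels = c("PD1hi", "Ki67pos")) {
  kind <- match.arg(kind)
  stopifnot(inherits(window, "tissue_window"), length(labels) == 2)
  if (mu_b < 0) stop("mu_b must be non-negative", call. = FALSE)
  check_thomas_params(kappa, mu_a, sigma, window)
  if (!is.null(seed)) set.seed(seed)
  pa <- thomas_parents(kappa, window, buffer = 4 * sigma)
  a <- thomas_offspring(pa, mu_a, sigma, window, labels[1])
  pb <- if (kind == "linked") pa else thomas_parents(kappa, window, 4 * sigma)
  b <- if (mu_b > 0) thomas_offspring(pb, mu_b, sigma, window, labels[2])
       else new_pattern(numeric(0), numeric(0), labels[2])
  if (kind == "independent") b$parent_id <- b$parent_id + nrow(pa)
  rbind(a, b)
}

#' Default per-phenotype marker intensity models
#'
#' Log-normal location/scale (meanlog, sdlog) per marker channel per
#' phenotype, on an arbitrary staining-intensity scale. Class locations are
#' separated by 12 sdlog units on every discriminating channel, so threshold
#' gating recovers the generating labels exactly; the PD1 channel is bimodal
#' across a mixed population (high for Tfh, low otherwise), mirroring the
#' high/low PD1 dichotomy used to define Tfh cells.
#'
#' @return Named list: phenotype -> channel -> `c(meanlog, sdlog)`.
#' @export
intensity_models_default <- function() {
  sd <- 0.25
  list(
    Tfh   = list(CD4 = c(4, sd), PD1 = c(5, sd), FOXP3 = c(1, sd), Ki67 = c(1, sd)),
    Treg  = list(CD4 = c(4, sd), PD1 = c(2, sd), FOXP3 = c(4, sd), Ki67 = c(1, sd)),
    Ki67pos = list(CD4 = c(1, sd), PD1 = c(2, sd), FOXP3 = c(1, sd), Ki67 = c(4, sd)),
    other = list(CD4 = c(4, sd), PD1 = c(2, sd), FOXP3 = c(1, sd), Ki67 = c(1, sd))
  )
}

#' Attach synthetic marker intensities to a labelled pattern
#'
#' Draws one intensity per marker channel per cell from the cell's
#' phenotype-specific log-normal model, producing a cell table suitable for
#' the gating stage while retaining the generating (ground-truth) labels.
#'
#' @param pattern A labelled pattern (`x`, `y`, `label`, `parent_id`).
#' @param models Intensity models as from [intensity_models_default()]; every
#'   label present in `pattern` must have a model for every channel.
#' @param channels Marker channel names to generate.
#' @param seed Optional integer seed.
#' @return A cell table: `cell_id`, `x`, `y`, one column per channel,
#'   `true_label`, `parent_id`.
#' @export
attach_intensities <- function(pattern, models = intensity_models_default(),
                               channels = c("CD4", "PD1", "FOXP3", "Ki67"),
                               seed = NULL) {
  labs <- unique(pattern$label)
  for (l in labs) {
    if (is.null(models[[l]])) {
      stop(sprintf("no intensity model for phenotype '%s'", l), call. = FALSE)
    }
    missing_ch <- setdiff(channels, names(models[[l]]))
    if (length(missing_ch)) {
      stop(sprintf("phenotype '%s' lacks a model for channel(s): %s",
                   l, paste(missing_ch, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pattern)
  out <- data.frame(cell_id = seq_len(n), x = pattern$x, y = pattern$y)
  for (ch in channels) {
    v <- numeric(n)
    for (l in labs) {
      idx <- which(pattern$label == l)
      par <- models[[l]][[ch]]
      v[idx] <- stats::rlnorm(length(idx), meanlog = par[1], sdlog = par[2])
    }
    out[[ch]] <- v
  }
  out$true_label <- pattern$label
  out$parent_id <- pattern$parent_id
  out
}

#' Default parameters of the full-tissue scenario
#'
#' One synthetic "case": a 4 mm^2 window holding four populations —
#' a Thomas-clustered Tfh analogue, a spatially random Treg analogue, a
#' proliferating Ki-67+ population sharing the Tfh cluster parents (linked),
#' and a spatially random CD4+ background. Rates are chosen so that the
#' gated Tfh + Treg + Tfr fraction of CD4+ cells lands near the 16% reported
#' for marginal zone lymphoma sections.
#'
#' @return Named list of scenario parameters.
#' @export
full_tissue_params <- function() {
  list(
    window = tissue_window(0, 0, 2000, 2000),
    tfh = list(kappa = 5e-6, mu = 15, sigma = 30),
    ki67 = list(mu = 40, sigma = 30), # shares the Tfh parents
    treg_lambda = 5e-5,
    background_lambda = 6.5e-4
  )
}

#' Simulate a full-tissue case
#'
#' Generates the four-population scenario of [full_tissue_params()] and
#' attaches marker intensities, using per-population sub-streams of the one
#' global seed (see [derive_seed()]).
#'
#' @param seed Integer seed for the case.
#' @param params Scenario parameters, defaulting to [full_tissue_params()].
#' @param models Intensity models.
#' @return A cell table as from [attach_intensities()].
#' @export
simulate_full_tissue <- function(seed, params = full_tissue_params(),
                                 models = intensity_models_default()) {
  w <- params$window
  tfh_sigma <- params$tfh$sigma
  set.seed(derive_seed(seed, "parents"))
  parents <- thomas_parents(params$tfh$kappa, w, buffer = 4 * tfh_sigma)
  set.seed(derive_seed(seed, "tfh"))
  tfh <- thomas_offspring(parents, params$tfh$mu, tfh_sigma, w, "Tfh")
  set.seed(derive_seed(seed, "ki67"))
  ki67 <- thomas_offspring(parents, params$ki67$mu, params$ki67$sigma, w,
                           "Ki67pos")
  treg <- simulate_csr(params$treg_lambda, w,
                       seed = derive_seed(seed, "treg"), label = "Treg")
  bg <- simulate_csr(params$background_lambda, w,
                     seed = derive_seed(seed, "background"), label = "other")
  pattern <- rbind(tfh, ki67, treg, bg)
  attach_intensities(pattern, models = models,
                     seed = derive_seed(seed, "intensities"))
}

#' Simulate a PD1-high reference population
#'
#' Stands in for tonsillar germinal-centre Tfh cells: the reference
#' population whose PD1 intensity distribution calibrates the PD1-high
#' threshold. Cells are drawn from the Tfh intensity model only.
#'
#' @param n Number of reference cells.
#' @param seed Optional integer seed.
#' @param models Intensity models (the `Tfh` entry is used).
#' @return A cell table with intensity columns and `true_label = "Tfh"`.
#' @export
simulate_reference_tfh <- function(n = 2000, seed = NULL,
                                   models = intensity_models_default()) {
  stopifnot(n >= 1)
  grid <- max(1, ceiling(sqrt(n)))
  xy <- expand.grid(x = seq_len(grid), y = seq_len(grid))[seq_len(n), ]
  pattern <- new_pattern(xy$x * 10, xy$y * 10, "Tfh")
  attach_intensities(pattern, models = models, seed = seed)
}
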