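#' Extract a phenotype's coordinates from gated calls
#'
#' Selects the cells of a phenotype as a point set for the spatial stages.
#' Surrogate phenotypes map to single-marker flags (`PD1hi` -> `pd1_hi`,
#' `FOXP3pos` -> `foxp3_pos`, `Ki67pos` -> `ki67_pos`); other names match
#' the `phenotype` column. `exclude_ki67 = TRUE` restricts to
#' Ki-67-negative cells, the convention for nearest-neighbour queries
#' against the proliferating population (a proliferating PD1-high cell must
#' not measure distance to itself).
#'
#' @param calls Phenotype calls from [gate_cells()].
#' @param phenotype Phenotype or surrogate name.
#' @param exclude_ki67 Drop Ki-67-positive cells.
#' @return Data frame with `cell_id`, `x`, `y`.
#' @export
phenotype_points <- function(calls, phenotype, exclude_ki67 = FALSE) {
  sel <- switch(phenotype,
                PD1hi = calls$pd1_hi,
                FOXP3pos = calls$foxp3_pos,
                Ki67pos = calls$ki67_pos,
                CD4pos = calls$cd4_pos,
                calls$phenotype == phenotype)
  if (exclude_ki67) sel <- sel & !calls$ki67_pos
  calls[sel, c("cell_id", "x", "y")]
}

analyse_case <- function(case_id, cells, window, config, radii, sides,
                         min_cells, high_threshold, nn_max, seed) {
  calls <- gate_cells(cells, config)
  summary <- subset_summary(calls)
  kfuns <- lapply(c(PD1hi = "PD1hi", FOXP3pos = "FOXP3pos"), function(p) {
    ripley_k(phenotype_points(calls, p), window, radii)
  })
  ki67 <- phenotype_points(calls, "Ki67pos")
  interactions <- lapply(c(PD1hi = "PD1hi", FOXP3pos = "FOXP3pos"),
                         function(p) {
    multiscale_interaction(phenotype_points(calls, p), ki67, window,
                           sides = sides, min_cells = min_cells,
                           high_threshold = high_threshold)
  })
  nn <- lapply(c(PD1hi = "PD1hi", FOXP3pos = "FOXP3pos"), function(p) {
    q <- phenotype_points(calls, p, exclude_ki67 = TRUE)
    nn_seed <- derive_seed(seed, paste0(case_id, "/nn/", p))
    if (nrow(q) > nn_max) q <- sample_queries(q, nn_max, seed = nn_seed)
    res <- cross_nn_distances(q, ki67, query_label = paste0("Ki67neg", p),
                              target_label = "Ki67pos")
    res$seed <- nn_seed
    res
  })
  list(case_id = case_id, n_cells = nrow(cells), calls = calls,
       summary = summary, kfuns = kfuns, interactions = interactions,
       nn = nn)
}

#' Run the full spatial analysis pipeline
#'
#' Chains every stage over a set of cases: gating (with PD1-high threshold
#' calibrated on a reference population), subset summaries, Ripley's K and
#' cluster scores for the PD1-high and FOXP3+ surrogates, multiscale quadrat
#' co-localization of each against the Ki-67+ population, cross-type
#' nearest-neighbour distances, and the cross-case comparisons (cluster
#' scores, pooled NN distances, surrogate regression, optional group
#' comparison of per-case densities). When no cases are supplied, a seeded
#' synthetic cohort of full-tissue cases is generated.
#'
#' A case whose analysis fails is recorded under `case_errors` and the
#' remaining cases proceed. With identical inputs and seed the report is
#' identical, including the JSON written to `out_dir`.
#'
#' @param cases Named list of `list(cells =, window =)` per case, or `NULL`
#'   to simulate `n_cases` full-tissue cases.
#' @param n_cases Number of synthetic cases when `cases` is `NULL`.
#' @param seed Global seed; expanded into per-stage sub-streams with
#'   [derive_seed()].
#' @param params Scenario parameters for synthetic cases.
#' @param config A [gating_config()]; `pd1_high` is calibrated from
#'   `reference` when unset.
#' @param reference Reference cell table for PD1 calibration, or `NULL` to
#'   simulate one.
#' @param sides Quadrat side lengths (um).
#' @param min_cells,high_threshold Quadrat filter and high-interaction
#'   cutoff.
#' @param nn_max Ceiling on nearest-neighbour query cells per case and
#'   phenotype; more are subsampled ([sample_queries()]).
#' @param groups Optional per-case group labels for [group_compare()] of
#'   per-case PD1-high and FOXP3+ cell densities.
#' @param out_dir If non-`NULL`, writes `report.json` and `summary.md`
#'   there.
#' @return List of class `tme_pipeline_report`.
#' @export
run_pipeline <- function(cases = NULL, n_cases = 6, seed = 1,
                         params = full_tissue_params(),
                         config = gating_config(), reference = NULL,
                         sides = c(100, 200, 400), min_cells = 5,
                         high_threshold = 50, nn_max = 1e5,
                         groups = NULL, out_dir = NULL) {
  if (is.null(cases)) {
    if (n_cases < 1) stop("empty case list", call. = FALSE)
    case_ids <- sprintf("case%02d", seq_len(n_cases))
    cases <- lapply(case_ids, function(id) {
      list(cells = simulate_full_tissue(derive_seed(seed, id),
                                        params = params),
           window = params$window)
    })
    names(cases) <- case_ids
  }
  if (length(cases) == 0) stop("empty case list", call. = FALSE)
  if (is.null(names(cases)) || anyNA(names(cases)) ||
      any(names(cases) == "")) {
    names(cases) <- sprintf("case%02d", seq_along(cases))
  }
  if (is.null(reference)) {
    reference <- simulate_reference_tfh(2000,
                                        seed = derive_seed(seed, "reference"))
  }
  if (is.null(config$pd1_high)) {
    config <- calibrate_pd1_threshold(reference, config)
  }
  results <- list()
  case_errors <- list()
  for (id in names(cases)) {
    res <- tryCatch(
      analyse_case(id, cases[[id]]$cells, cases[[id]]$window, config,
                   radii = NULL, sides = sides, min_cells = min_cells,
                   high_threshold = high_threshold, nn_max = nn_max,
                   seed = seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      case_errors[[id]] <- conditionMessage(res)
    } else {
      results[[id]] <- res
    }
  }
  if (length(results) == 0) {
    stop("all cases failed: ", paste(unlist(case_errors), collapse = "; "),
         call. = FALSE)
  }
  score <- function(pheno) vapply(results, function(r)
    r$kfuns[[pheno]]$cluster_score, numeric(1))
  pooled_nn <- function(pheno) unlist(lapply(results, function(r)
    r$nn[[pheno]]$distances), use.names = FALSE)
  mid_side <- as.character(sides[ceiling(length(sides) / 2)])
  mh <- function(pheno) vapply(results, function(r)
    r$interactions[[pheno]][[mid_side]]$morisita_horn, numeric(1))
  comparisons <- list(
    cluster_scores = compare_cluster_scores(score("PD1hi"),
                                            score("FOXP3pos")),
    nn_distances = compare_nn(pooled_nn("PD1hi"), pooled_nn("FOXP3pos")),
    morisita_horn = rank_sum_test(mh("PD1hi"), mh("FOXP3pos"),
                                  what = "Morisita-Horn index"),
    surrogate = tryCatch(
      surrogate_agreement(lapply(results, `[[`, "calls")),
      error = function(e) conditionMessage(e))
  )
  if (!is.null(groups)) {
    density_of <- function(flag) vapply(names(results), function(id) {
      sum(results[[id]]$calls[[flag]]) / window_area(cases[[id]]$window)
    }, numeric(1))
    g <- groups[names(results)]
    comparisons$group_density <- list(
      pd1hi = group_compare(density_of("pd1_hi"), g),
      foxp3 = group_compare(density_of("foxp3_pos"), g))
  }
  report <- structure(list(
    seed = seed,
    pd1_high_threshold = config$pd1_high,
    n_cases = length(results),
    cases = results,
    case_errors = case_errors,
    comparisons = comparisons,
    settings = list(sides = sides, min_cells = min_cells,
                    high_threshold = high_threshold, nn_max = nn_max,
                    multiplicity_adjustment = "none")
  ), class = "tme_pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.tme_pipeline_report <- function(x, ...) {
  cat(sprintf("spatial TME pipeline: %d case(s), seed %d\n", x$n_cases,
              x$seed))
  cat(sprintf("  PD1-high threshold %.4g (calibrated)\n",
              x$pd1_high_threshold))
  cs <- x$comparisons$cluster_scores
  cat(sprintf("  cluster score medians: PD1hi %.3f vs FOXP3+ %.3f (p = %.3g)\n",
              cs$median_a, cs$median_b, cs$p_value))
  nn <- x$comparisons$nn_distances
  cat(sprintf("  NN medians to Ki67+: PD1hi %.2f um vs FOXP3+ %.2f um (p = %.3g)\n",
              nn$median_a, nn$median_b, nn$p_value))
  mh <- x$comparisons$morisita_horn
  cat(sprintf("  Morisita-Horn medians vs Ki67+: PD1hi %.3f vs FOXP3+ %.3f\n",
              mh$median_a, mh$median_b))
  if (length(x$case_errors)) {
    cat(sprintf("  %d case(s) failed: %s\n", length(x$case_errors),
                paste(names(x$case_errors), collapse = ", ")))
  }
  cat("  raw p-values; no multiplicity adjustment applied\n")
  invisible(x)
}

# Strip heavyweight per-cell tables and unclass everything for JSON.
report_for_json <- function(report) {
  rep2 <- unclass(report)
  rep2$cases <- lapply(report$cases, function(r) {
    list(case_id = r$case_id, n_cells = r$n_cells,
         summary = unclass(r$summary),
         cluster_scores = lapply(r$kfuns, function(k)
           list(n = k$n, correction = k$correction,
                cluster_score = k$cluster_score)),
         interactions = lapply(r$interactions, function(il)
           lapply(il, unclass)),
         nn = lapply(r$nn, function(nnr)
           list(n_query = nnr$n_query, n_target = nnr$n_target,
                median = nnr$median, seed = nnr$seed)))
  })
  rep2$comparisons <- lapply(report$comparisons, function(cmp) {
    if (is.list(cmp) && !is.null(cmp$histogram)) cmp$histogram <- NULL
    if (inherits(cmp, "rank_test") || inherits(cmp, "group_test")) {
      unclass(cmp)
    } else cmp
  })
  rep2
}

#' Write a pipeline report to disk
#'
#' `report.json` holds the machine-readable report (per-cell tables
#' excluded); `summary.md` is the human-readable digest. Output is
#' deterministic given the same report.
#'
#' @param report A `tme_pipeline_report`.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_for_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE, pretty = TRUE)
  md <- utils::capture.output(print(report))
  writeLines(c("# Spatial TME pipeline summary", "", "```", md, "```"),
             file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
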