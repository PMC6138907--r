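# spatialTME

Spatial statistics for CD4+ T-cell subsets in multiplex-IHC tissue
sections, with seeded synthetic-tissue generators.

## The science

Multiplex immunohistochemistry of lymphoma tissue (markers CD4, PD1,
FOXP3, Ki-67) produces a table of segmented cells: coordinates in
micrometres plus per-marker staining intensities. The biological questions
are whether follicular-helper-like T cells (PD1-high) and regulatory
T cells (FOXP3+) are spatially clustered rather than randomly scattered,
and whether the PD1-high subset co-localizes with the proliferating
(Ki-67+) tumour compartment, as Tfh "helper" biology predicts.

The package implements the full analysis chain:

* **Gating** — threshold rules on marker intensities call each cell Tfh
  (CD4+ PD1≥τ FOXP3−), Tfr (CD4+ PD1≥τ FOXP3+), Treg (CD4+ PD1<τ FOXP3+)
  or other, with τ calibrated as the 5th percentile of PD1 in a reference
  PD1-high population (tonsillar-Tfh analogue) or estimated from channel
  bimodality.
* **Ripley's K** — for each phenotype's point set,

      K̂(r) = |A| / (n(n−1)) · Σ_{i≠j} w_ij · 1(d_ij ≤ r)

  with translation edge correction, compared with the CSR expectation
  πr². The curve is reduced to a **cluster score**
  S = ∫(K̂ − πr²)dr / ∫πr² dr: 0 under complete spatial randomness,
  positive for clustering, negative for regularity.
* **Quadrat co-localization** — square tessellations (100/200/400 μm
  sides); per scale the Pearson correlation of counts, the Morisita-Horn
  overlap index

      MH = 2 Σ xᵢyᵢ / [(Σxᵢ²/X² + Σyᵢ²/Y²) · X · Y]

  and the fraction of quadrats with >50 cells of both types.
* **Nearest neighbours** — exact distance from every Ki-67-negative query
  cell to the nearest Ki-67+ cell (compiled plane sweep), pooled across
  cases and compared between phenotypes by Mann-Whitney test.
* **Synthetic tissue** — seeded generators (CSR, Thomas cluster process,
  linked/independent bivariate processes, log-normal marker intensities)
  whose defaults mimic a marginal-zone-lymphoma-like section, so the whole
  pipeline is demonstrable and testable without patient coordinates.

The estimators (K with translation correction, Thomas simulator, quadrat
statistics, nearest-neighbour search) are implemented here directly — they
are the point of the package — and each is verified against an independent
brute-force oracle in the test suite. Details, formulas, parameter
rationale and limitations are in the methods vignette,
`vignettes/spatial-tme-methods.Rmd`.

## Worked example

```r
library(spatialTME)

cells <- simulate_full_tissue(seed = 7)              # one synthetic case
ref   <- simulate_reference_tfh(seed = 8)            # tonsil-like reference
cfg   <- calibrate_pd1_threshold(ref, gating_config())
cat("tau_PD1:", cfg$pd1_high, "\n")
#> tau_PD1: 96.9356

calls <- gate_cells(cells, cfg)
print(subset_summary(calls))
#> 3989 cells gated; 3204 CD4+ (307 PD1hi, 206 FOXP3+, 785 Ki67+)
#>   Tfh       307
#>   Treg      206
#>   Tfr         0
#>   other    3476
#>   Tfh+Treg+Tfr = 16.0% of CD4+
#>   PD1hi:FOXP3+ ratio = 1.49

win <- full_tissue_params()$window
print(ripley_k(phenotype_points(calls, "PD1hi"), win))
#> Ripley's K: 307 points, translation correction, r in [0, 500] um
#>   cluster score 0.432 (0 = CSR, > 0 = clustered)

ms <- multiscale_interaction(phenotype_points(calls, "PD1hi"),
                             phenotype_points(calls, "Ki67pos"), win)
print(ms[["200"]])
#> quadrat interaction at side 200 um (31/100 quadrats analysed)
#>   Pearson 0.867 | Morisita-Horn 0.957 | high-interaction 0.0%

nn <- cross_nn_distances(phenotype_points(calls, "PD1hi", exclude_ki67 = TRUE),
                         phenotype_points(calls, "Ki67pos"),
                         "PD1hi", "Ki67pos")
print(nn)
#> nearest-neighbour distances PD1hi -> Ki67pos: 307 queries, 785 targets
#>   median 7.92 um (IQR 4.81-12.52)
```

The single-case pattern holds at cohort level: `run_pipeline(n_cases = 6,
seed = 1)` gives per-case cluster-score medians of 0.67 for PD1-high
versus 0.002 for FOXP3+ cells (rank-sum p = 0.0039), Morisita-Horn with
the Ki-67+ compartment of 0.96 versus 0.31 at 200 μm, and pooled
nearest-neighbour medians of 8.4 μm versus 153.4 μm — the PD1-high subset
is strongly clustered and sits against the proliferating population, while
the FOXP3+ subset is CSR-like and spatially indifferent to it.

## Analysis workflow

The study itself is organised as numbered drivers under `analysis/`,
each a thin script over the package API writing text tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # 6 cases + reference -> results/cells/
Rscript analysis/02_gating.R               # calibration, calls, subset summaries
Rscript analysis/03_clustering.R           # per-case cluster scores + comparison
Rscript analysis/04_colocalization.R       # multiscale quadrat statistics
Rscript analysis/05_nearest_neighbours.R   # pooled NN distances + comparison
Rscript analysis/06_full_pipeline.R        # the one-call equivalent (report.json)
```

Stages 2–5 read the outputs of stage 1, so run them in order (or just
stage 6, which is self-contained).

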