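---
title: "Spatial analysis of T-cell subsets in the tumour microenvironment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial analysis of T-cell subsets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialTME)
```

# The problem

Multiplex immunohistochemistry of lymphoma tissue yields, after image
registration and nucleus segmentation, one row per detected cell: planar
coordinates in micrometres plus a staining intensity per marker (here CD4,
PD1, FOXP3, Ki-67). Two questions about infiltrating CD4+ T-cell subsets
follow. First, are follicular-helper-like cells (PD1-high) and regulatory
cells (FOXP3+) randomly scattered through the tissue or clustered? Second,
do they co-localize with the proliferating (Ki-67+, largely B-cell)
population — as Tfh biology predicts for the PD1-high subset?

This package implements that analysis as a reproducible pipeline:
phenotype gating from intensities, Ripley's-K clustering scores against
complete spatial randomness (CSR), quadrat-based co-localization (Pearson
and Morisita-Horn), and cross-type nearest-neighbour distances. Because
patient cell coordinates from such studies are generally not deposited, the
package also ships seeded generators for marked point patterns with the
relevant structure, so every stage is testable end to end and the
qualitative findings can be reproduced on synthetic cohorts.

# Phenotype gating

Subset definitions are threshold rules on marker intensities, with boundary
values counted positive:

| CD4 | PD1          | FOXP3 | call  |
|-----|--------------|-------|-------|
| +   | >= tau_PD1   | −     | Tfh   |
| +   | >= tau_PD1   | +     | Tfr   |
| +   | <  tau_PD1   | +     | Treg  |
| any other combination |||  other |

Independently of the subset call, the single-marker surrogate flags
`pd1_hi` (regardless of CD4/FOXP3) and `foxp3_pos` are emitted; the
`surrogate_agreement()` regression (OLS of subset count on surrogate count
across cases) quantifies how safely a single marker stands in for the
multi-marker subset.

**PD1-high threshold.** `tau_PD1` is anchored on a reference population
known to be PD1-high — in the original setting, Tfh cells of tonsillar
germinal centres. `calibrate_pd1_threshold()` sets it to the `q_ref`
quantile of the reference PD1 intensities (type-7 linear-interpolation
quantiles, fixed). The default `q_ref = 0.05` makes 95% of reference cells
PD1-high. Note the structural consequence: if the tissue's PD1-high cells
are drawn from the same distribution as the reference, about `q_ref` of
them fall below any such threshold. Exact recovery of generating labels is
therefore only possible with a threshold in the gap between the low and
high modes; when no `pd1_high` is configured, `gate_cells()` estimates one
that way (below).

**Positivity thresholds.** Proprietary image-analysis systems do not
publish their positivity criteria, so per-channel thresholds default to a
bimodality split: a Gaussian kernel density estimate of the
log-intensities, the two dominant modes located (a second mode counts only
if the density dips below half its height between the two — plain KDE local
maxima are jittery on a heavy single mode), and the threshold placed midway
between them on the log scale. The log scale suits strictly positive,
right-skewed staining intensities. Every threshold is overridable in
`gating_config()`, and a channel that is not bimodal raises an error
rather than guessing.

# Clustering: Ripley's K and the cluster score

For a phenotype's point set in a rectangular window of area $|A|$,

$$\hat K(r) = \frac{|A|}{n(n-1)} \sum_{i \ne j} w_{ij}\, \mathbf 1(d_{ij} \le r),$$

with translation edge-correction weights
$w_{ij} = |A| / \big((a - |dx_{ij}|)(b - |dy_{ij}|)\big)$, exact for
rectangles. Under CSR, $K(r) = \pi r^2$. The default radius grid is 50
points from 0 to a quarter of the shorter window side — the usual guard
beyond which edge correction degrades; larger grids are refused. Only
`"translation"` and `"none"` corrections are provided: translation is
already exact for the rectangular windows that are the only supported
geometry (irregular tissue masks are approximated by the bounding
rectangle of the cells — an acknowledged simplification whose effect on
edge correction is not quantified here).

The scalar **cluster score** reduces the observed-vs-CSR gap to one
number:

$$S = \frac{\int \big(\hat K(r) - \pi r^2\big)\,dr}{\int \pi r^2\,dr}$$

(trapezoidal, over the radius grid). Zero for CSR, positive for
clustering — $S = 1$ exactly when $\hat K = 2\pi r^2$ throughout — and
negative for regularity; the normalization makes it dimensionless and
window-scale-free. The score's definition is this package's own (studies
reporting "the difference between the curves" rarely write the formula);
published patient medians for such scores are therefore directional
references, not values this score must reproduce. Whether a variance-
stabilized L-function would have been used instead is unknowable from the
outside; K was chosen because the score then has the clean $S=1$
interpretation above.

# Quadrat co-localization

`tessellate()` divides the window into non-overlapping squares of side
$s$ anchored at the lower-left corner; partial edge strips are dropped
(quadrats must be equally sized) and cells in them are excluded. Cell
assignment uses half-open intervals, so boundary cells count exactly once.
Quadrat sides are lengths (100, 200, 400 um by default): a "quadrat" of
*area* 200 um² (side 14 um) could never hold the >50 cells of the
high-interaction rule, so the side-length reading is the only coherent
one.

Per tessellation, for count vectors $x$ (type A) and $y$ (type B):

* **Pearson correlation**, over quadrats passing the display filter
  $\max(x_i, y_i) \ge$ `min_cells` (default 5); fewer than 3 passing
  quadrats is an error, constant filtered counts give `NA` with a warning.
* **Morisita-Horn index**
  $MH = 2\sum x_i y_i \,/\, \big[(\sum x_i^2/X^2 + \sum y_i^2/Y^2)\,XY\big]$,
  in $[0,1]$, computed over *all* retained quadrats — it is a
  whole-tessellation overlap index, so the display filter does not apply by
  default (`filter_mh = TRUE` restores the filtered variant).
* **High-interaction fraction**: quadrats with strictly more than
  `high_threshold` (default 50) cells of *both* types, as a fraction of the
  filter-passing ("analysed") quadrats.

`multiscale_interaction()` repeats all three at each side and flags Pearson
sign changes across scales.

# Nearest neighbours

`cross_nn_distances()` returns, for every query cell, the exact Euclidean
distance to the nearest target cell, via a compiled plane sweep over
targets sorted by x (verified identical to the brute-force scan in the
test suite). Queries are restricted to Ki-67-negative cells of the query
phenotype (`phenotype_points(..., exclude_ki67 = TRUE)`) so a proliferating
PD1-high cell never measures the distance to itself. Distances are computed
within a case and pooled afterwards, never across tissue-section
boundaries. Samples larger than `nn_max` (default $10^5$, mirroring common
practice) are subsampled without replacement, seeded, optionally stratified
by case with proportional largest-remainder allocation.

# Rank-based comparisons

All two-group comparisons (cluster scores, NN distances, per-case indices)
use the two-sided Mann-Whitney rank-sum test; `group_compare()` dispatches
to Kruskal-Wallis for three or more groups. The tie-corrected normal
approximation without continuity correction is used throughout, so
identical groups give p = 1 exactly. No multiplicity adjustment is applied
— the pipeline reports raw p-values and says so in its output; adjust with
`p.adjust` downstream if desired.

# The synthetic-data generators

The generators provide the statistical structure the analysis assumes,
not images:

* `simulate_csr()`: homogeneous Poisson — the null, and the Treg
  analogue.
* `simulate_thomas()`: Thomas/Neyman-Scott cluster process — the PD1-high
  analogue. Parents are simulated on the window expanded by $4\sigma$ per
  side and offspring clipped to the window, so clusters near the boundary
  are not artificially thinned and the expected retained count is
  $\kappa |A| \mu$.
* `simulate_bivariate()`: two classes either sharing Thomas parents
  ("linked" — the Ki-67+/PD1-high situation) or with independent parent
  sets. Calling both arms with the *same seed* makes the first class
  identical in both, giving a properly paired contrast in which only the
  second class's linkage differs.
* `attach_intensities()`: log-normal intensities per channel per
  phenotype. Log-normal because staining intensities are strictly positive
  and right-skewed. Default class locations differ by 12 sdlog units on
  every discriminating channel, so threshold gating is exact up to
  $\Phi(-6) \approx 10^{-9}$ per draw; the PD1 channel is bimodal across a
  mixed population.

**Full-tissue scenario** (`full_tissue_params()`): a 2000 x 2000 um window
(4 mm²) — desk-scale against real whole sections of 4.8–112 mm², chosen so
a six-case cohort analyses in seconds — holding a clustered Tfh analogue
(Thomas, $\kappa = 5\times10^{-6}$/um², $\mu = 15$, $\sigma = 30$ um), a
Ki-67+ population sharing the Tfh parents ($\mu = 40$), a CSR Treg
analogue ($\lambda = 5\times10^{-5}$/um²) and a CSR CD4+ background
($\lambda = 6.5\times10^{-4}$/um²). The rates put the gated
Tfh + Treg + Tfr fraction of CD4+ cells near 16%, matching the order
reported for marginal zone lymphoma, with per-case densities of a few
hundred cells/mm² for the subsets. Tfr cells are not generated (they are a
rare population in this setting); the Tfr gate is still exercised by unit
tests. The paired co-localization scenario uses $\kappa = 5\times10^{-5}$
parents/um², $\mu = 20$ offspring per class and $\sigma = 20$ um: about
1000 cells per class per mm² in foci of follicle-fragment scale, dense
enough that the >50-cell high-interaction rule discriminates linked from
independent arms.

One global seed is expanded into named sub-streams (`derive_seed()`), so
adding a pipeline stage does not perturb the draws of earlier stages, and
every stochastic step's seed is recorded in the pipeline report.

**What the generators do not emulate.** Homogeneous backgrounds (no
within-slide intensity gradients), rectangular windows (no irregular
section outlines or holes), independent log-normal channels (no spectral
bleed-through, no segmentation-induced intensity correlations), and no
spatial dependence between intensity and position. Passing tests therefore
demonstrate the estimators' correctness and the detectability of the
designed spatial contrasts — not robustness to inhomogeneity, masking or
staining artefacts in patient material.

# Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation), everywhere.
* K estimation requires >= 2 points; radius grids must be strictly
  increasing, start at >= 0, and respect the quarter-side guard.
* Fractions with zero denominators are `NA` ("undefined"), never 0; the
  PD1hi:FOXP3+ ratio with no FOXP3+ cells is `Inf`, not an error.
* Empty query or target sets for nearest neighbours are errors; coincident
  points legitimately give distance 0.
* A `sigma` above half the shorter window side warns that cluster
  structure is unresolvable; simulation proceeds (the infinite-dispersion
  limit is CSR).
* Nearest-target ties need no tie-break (the distance, not the identity,
  is returned).
* Cell tables are written with 9 significant digits; round trips are exact
  to that precision.

# Known limitations

Rectangular windows only; no inhomogeneous K, pair-correlation or
cross-K functions; no simulation-envelope significance bands (envelopes
appear only as test machinery); no G/F nearest-neighbour distribution
inference; no image ingestion. The per-case analysis sizes used by the
test suite and the reproduction script (1 mm² windows for calibration
cohorts, 4 mm² six-case pipelines, 100-replicate Monte-Carlo batches) were
chosen as the smallest at which the Monte-Carlo tolerances asserted are
comfortably stable.
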