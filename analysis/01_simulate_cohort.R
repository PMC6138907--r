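#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort the rest of the analysis runs on.
# Six full-tissue cases (4 mm^2 each; clustered Tfh analogue, linked Ki-67+
# population, random Treg analogue, CD4+ background) plus the PD1-high
# reference population used to calibrate the gating threshold.

library(spatialTME)

seed <- 1
out_dir <- "results/cells"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

params <- full_tissue_params()
for (i in 1:6) {
  id <- sprintf("case%02d", i)
  cells <- simulate_full_tissue(derive_seed(seed, id), params = params)
  write_cell_table(cells, file.path(out_dir, paste0(id, ".csv")),
                   window = params$window)
  cat(sprintf("%s: %d cells (%s)\n", id, nrow(cells),
              paste(sprintf("%s=%d", names(table(cells$true_label)),
                            table(cells$true_label)), collapse = ", ")))
}

reference <- simulate_reference_tfh(2000, seed = derive_seed(seed, "reference"))
write_cell_table(reference, file.path(out_dir, "reference_tfh.csv"))
cat(sprintf("reference population: %d cells, PD1 median %.1f\n",
            nrow(reference), median(reference$PD1)))
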