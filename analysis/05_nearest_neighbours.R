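#!/usr/bin/env Rscript
# Stage 5: nearest-neighbour analysis. Distance from every Ki-67-negative
# PD1-high (and FOXP3+) cell to the nearest Ki-67+ cell, pooled across
# cases, with medians and the rank-sum comparison between the two query
# phenotypes.

library(spatialTME)

call_dir <- "results/gating"
out_dir <- "results/neighbours"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

call_files <- sort(list.files(call_dir, pattern = "_calls\\.csv$",
                              full.names = TRUE))
pooled <- list(PD1hi = list(), FOXP3pos = list())
for (path in call_files) {
  id <- sub("_calls\\.csv$", "", basename(path))
  calls <- utils::read.csv(path)
  ki67 <- phenotype_points(calls, "Ki67pos")
  for (pheno in names(pooled)) {
    q <- phenotype_points(calls, pheno, exclude_ki67 = TRUE)
    nn <- cross_nn_distances(q, ki67, query_label = pheno,
                             target_label = "Ki67pos")
    pooled[[pheno]][[id]] <- data.frame(case = id, phenotype = pheno,
                                        distance_um = nn$distances)
  }
}
distances <- do.call(rbind, c(pooled$PD1hi, pooled$FOXP3pos))
utils::write.csv(distances, file.path(out_dir, "nn_distances.csv"),
                 row.names = FALSE)

cmp <- compare_nn(distances$distance_um[distances$phenotype == "PD1hi"],
                  distances$distance_um[distances$phenotype == "FOXP3pos"])
print(cmp)
cat(sprintf("\nKi67-negative PD1hi cells sit %s to proliferating cells than FOXP3+ cells (%.1f vs %.1f um median).\n",
            if (cmp$median_a < cmp$median_b) "closer" else "no closer",
            cmp$median_a, cmp$median_b))
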