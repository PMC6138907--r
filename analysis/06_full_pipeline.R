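#!/usr/bin/env Rscript
# Stage 6: the one-call equivalent of stages 1-5. run_pipeline() simulates
# the cohort, calibrates, gates, scores clustering, quantifies quadrat
# co-localization and nearest neighbours, and performs the cross-case
# comparisons, writing report.json and summary.md.

library(spatialTME)

report <- run_pipeline(n_cases = 6, seed = 1, out_dir = "results/pipeline")
print(report)
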