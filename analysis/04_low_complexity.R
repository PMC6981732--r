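#!/usr/bin/env Rscript
# Iterative low-complexity masking (BLOSUM62 self-alignment, threshold 40)
# and LCAA% partitioned by region class. Low complexity should
# concentrate in the disordered non-domain regions where homopolymeric
# runs were planted.

library(idrscape)

cfg <- default_config(dir = "results/family", out_dir = "results/tables")
cfg$seed <- 1L
run_stage("cast", cfg)

lcaa <- read.delim(file.path(cfg$out_dir, "lcaa.tsv"))
cat("mean LCAA% by region class:\n")
print(round(tapply(lcaa$lcaa_percent, lcaa$region_class, mean, na.rm = TRUE), 2))

segs <- read.delim(file.path(cfg$out_dir, "low_complexity_segments.tsv"))
cat("\n", nrow(segs), "segments; dominant residues:\n")
print(sort(table(segs$residue), decreasing = TRUE))
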