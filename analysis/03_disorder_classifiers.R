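#!/usr/bin/env Rscript
# CH-CDF phase space and IDAA% by region view. Full-length and
# domain-deleted views are expected in the disordered quadrants (Q3/Q4),
# domains on the ordered side, with IDAA% highest outside the domain.

library(idrscape)

cfg <- default_config(dir = "results/family", out_dir = "results/tables")
cfg$seed <- 1L
run_stage("chcdf", cfg)
run_stage("idaa", cfg)

phase <- read.delim(file.path(cfg$out_dir, "phase_space.tsv"))
cat("quadrant occupancy by region view:\n")
print(table(phase$region_class, phase$quadrant))

idaa <- read.delim(file.path(cfg$out_dir, "idaa.tsv"))
cat("\nmean IDAA% by region view:\n")
print(round(tapply(idaa$idaa_percent, idaa$region_class, mean), 1))
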