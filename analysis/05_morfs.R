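#!/usr/bin/env Rscript
# MoRF candidates as order-propensity dips inside disordered regions,
# then subgroup-level conserved-MoRF calling: clusters of aligned dips
# with occupancy >= 0.75, named "<subgroup> N|C<index>", exclusivity
# flagged by cross-subgroup consensus similarity.

library(idrscape)

cfg <- default_config(dir = "results/family", out_dir = "results/tables")
cfg$seed <- 1L
run_stage("morfs", cfg)
run_stage("conserve", cfg)

cand <- read.delim(file.path(cfg$out_dir, "morf_candidates.tsv"))
cat(nrow(cand), "dip candidates across",
    length(unique(cand$id)), "proteins\n\n")
print(read.delim(file.path(cfg$out_dir, "conserved_morfs.tsv")))
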