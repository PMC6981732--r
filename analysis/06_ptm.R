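#!/usr/bin/env Rscript
# Phosphosite fraction statistics by residue type (S/T/Y) and region
# class. The toy site emissions put S/T phosphorylation mostly in the
# disordered regions and Y mostly in the domain, so the combined column
# partly offsets the S/T preference.

library(idrscape)

cfg <- default_config(dir = "results/family", out_dir = "results/tables")
cfg$seed <- 1L
run_stage("ptm", cfg)

ph <- read.delim(file.path(cfg$out_dir, "phospho_fractions.tsv"))
print(round(ph[, c("S", "T", "Y", "all")], 2))
cat("rows:", paste(ph$region_class, collapse = ", "), "\n")
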