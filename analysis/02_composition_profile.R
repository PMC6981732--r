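#!/usr/bin/env Rscript
# Relative compositional profiles (C_i - C_i^FSP)/C_i^FSP with
# whole-protein bootstrap CIs, for full-length, domain-only and
# domain-deleted views. The family should look disorder-promoting overall
# and even more so once the domain is removed, while the domain itself is
# W/A/R-enriched.

library(idrscape)

cfg <- default_config(dir = "results/family", out_dir = "results/tables")
cfg$seed <- 1L
run_stage("profile", cfg)

for (v in c("full", "ap2", "ap2_deleted")) {
  prof <- read.delim(file.path(cfg$out_dir, paste0("profile_", v, ".tsv")))
  signif_up <- prof$residue[prof$ci_low > 0]
  signif_dn <- prof$residue[prof$ci_high < 0]
  cat(sprintf("%-12s enriched: %-28s depleted: %s\n", v,
              paste(signif_up, collapse = " "),
              paste(signif_dn, collapse = " ")))
}
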