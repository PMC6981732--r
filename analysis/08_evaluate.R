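#!/usr/bin/env Rscript
# Score the whole run against the generator's planted ground truth:
# 50%-reciprocal-overlap matching for MoRF and low-complexity segments,
# exact labels for subgroups, topological distance for the tree.

library(idrscape)

cfg <- default_config(dir = "results/family", out_dir = "results/tables")
cfg$seed <- 1L
run_stage("eval", cfg)

metrics <- jsonlite::read_json(file.path(cfg$out_dir, "eval_metrics.json"),
                               simplifyVector = TRUE)
str(metrics)
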