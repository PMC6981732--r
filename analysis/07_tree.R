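#!/usr/bin/env Rscript
# Neighbour-joining tree from the p-distance matrix of the domain
# alignment, with column-resampling bootstrap support (100 replicates).
# Subgroups should come back as well-supported clades.

library(idrscape)

cfg <- default_config(dir = "results/family", out_dir = "results/tables")
cfg$seed <- 1L
run_stage("tree", cfg)

tree <- ape::read.tree(file.path(cfg$out_dir, "nj_tree.nwk"))
subgroups <- read_subgroups(file.path(cfg$dir, "subgroups.tsv"))
mono <- vapply(unique(subgroups), function(g)
  ape::is.monophyletic(tree, names(subgroups)[subgroups == g]), logical(1))
cat("monophyletic subgroups:", sum(mono), "/", length(mono), "\n")
flags <- read.delim(file.path(cfg$out_dir, "tree_support.tsv"))
cat("splits with support > 70%:", sum(flags$flagged, na.rm = TRUE),
    "of", nrow(flags), "\n")
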