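# Stage orchestration: a flat-ish config with defaults for every stage,
# deterministic artifact writing, and a run manifest with input/output
# digests.

#' Default pipeline configuration
#'
#' Nested list of every stage parameter with its default; any subset can
#' be overridden via \code{override}. Paths are resolved relative to
#' \code{dir} (inputs) and \code{out_dir} (artifacts).
#'
#' @param dir Input directory (a generated family or user data laid out
#'   the same way).
#' @param out_dir Artifact directory (default \code{file.path(dir,
#'   "results")}).
#' @param override Named list of overrides, e.g.
#'   \code{list(chcdf = list(boundary_a = 2.8))}.
#' @return Configuration list.
#' @export
default_config <- function(dir = ".", out_dir = file.path(dir, "results"),
                           override = list()) {
  cfg <- list(
    dir = dir, out_dir = out_dir, seed = 1L,
    simulate = list(n_subgroups = 4L, members_per_subgroup = 6L),
    profile = list(n_boot = 1000L, ci_level = 0.95),
    chcdf = list(boundary_a = 2.785, boundary_b = 1.151, window = 5L,
                 cdf_bins = cdf_bins()),
    idaa = list(threshold = 0.5),
    cast = list(threshold = 40),
    morfs = list(dip_threshold = 0.5, context_threshold = 0.5,
                 min_len = 5L, max_len = 25L, context = 10L),
    conserve = list(min_occupancy = 0.75, min_overlap_cols = 5L,
                    exclusive_identity = 0.6),
    tree = list(n_boot = 100L, support_cutoff = 70))
  modifyList(cfg, override)
}

#' Read a pipeline configuration file
#'
#' YAML with the same structure as \code{\link{default_config}}; missing
#' keys take defaults.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(dir = if (is.null(user$dir)) "." else user$dir)
  modifyList(cfg, user)
}

pipeline_stages <- function() {
  c("simulate", "profile", "chcdf", "idaa", "cast", "morfs", "conserve",
    "ptm", "tree")
}

req_file <- function(path) {
  if (!file.exists(path))
    stop("missing required input: ", path, call. = FALSE)
  path
}

load_family_inputs <- function(cfg) {
  dir <- cfg$dir
  seqs <- read_fasta(req_file(file.path(dir, "sequences.fasta")))
  regions <- read_region_table(file.path(dir, "regions.tsv"), seqs)
  tracks <- read_track(req_file(file.path(dir, "tracks.tsv")), seqs,
                       source = "external:tracks.tsv")
  subgroups <- read_subgroups(req_file(file.path(dir, "subgroups.tsv")))
  list(seqs = seqs, regions = regions, tracks = tracks,
       subgroups = subgroups)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: \code{simulate} (generate the synthetic family into
#' \code{cfg$dir}), \code{profile} (relative compositional profiles with
#' bootstrap CIs for the three region views), \code{chcdf} (phase-space
#' table), \code{idaa}, \code{cast} (low-complexity segments and LCAA%),
#' \code{morfs} (dip candidates), \code{conserve} (conserved-MoRF calls),
#' \code{ptm} (phosphosite fractions), \code{tree} (NJ + bootstrap
#' newick), \code{all} (everything in order) and \code{eval}
#' (ground-truth metrics, requires a simulated family). Each stage writes
#' TSV/JSON/newick artifacts into \code{cfg$out_dir} and updates
#' \code{manifest.json} with parameter and artifact digests; partial
#' outputs of a failing stage are removed.
#'
#' @param stage Stage name.
#' @param cfg Configuration from \code{\link{default_config}}.
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage, cfg = default_config()) {
  stages <- c(pipeline_stages(), "all", "eval")
  if (!stage %in% stages)
    stop("unknown stage: ", stage, " (expected one of ",
         paste(stages, collapse = ", "), ")")
  if (stage == "all") {
    paths <- unlist(lapply(pipeline_stages()[-1], run_stage, cfg = cfg))
    return(invisible(paths))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  res <- try({
    written <- switch(stage,
      simulate = stage_simulate(cfg),
      profile = stage_profile(cfg),
      chcdf = stage_chcdf(cfg),
      idaa = stage_idaa(cfg),
      cast = stage_cast(cfg),
      morfs = stage_morfs(cfg),
      conserve = stage_conserve(cfg),
      ptm = stage_ptm(cfg),
      tree = stage_tree(cfg),
      eval = stage_eval(cfg))
    update_manifest(stage, cfg, written)
    written
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    unlink(written)
    stop(attr(res, "condition"))
  }
  invisible(res)
}

#' Run the full pipeline
#'
#' \code{simulate} (unless the input directory already holds a family),
#' then every analysis stage, then \code{eval} when ground truth is
#' present.
#'
#' @param cfg Configuration list.
#' @return Invisibly, all artifact paths.
#' @export
run_pipeline <- function(cfg = default_config()) {
  paths <- character(0)
  if (!file.exists(file.path(cfg$dir, "sequences.fasta")))
    paths <- c(paths, run_stage("simulate", cfg))
  paths <- c(paths, run_stage("all", cfg))
  if (file.exists(file.path(cfg$dir, "truth.json")))
    paths <- c(paths, run_stage("eval", cfg))
  invisible(paths)
}

stage_simulate <- function(cfg) {
  spec <- family_spec(n_subgroups = cfg$simulate$n_subgroups,
                      members_per_subgroup = cfg$simulate$members_per_subgroup,
                      seed = cfg$seed)
  generate_family(spec, dir = cfg$dir)
  file.path(cfg$dir, c("sequences.fasta", "regions.tsv", "tracks.tsv",
                       "morfs.tsv", "phospho.tsv", "subgroups.tsv",
                       "tree.nwk", "ap2_alignment.fasta", "truth.json"))
}

stage_profile <- function(cfg) {
  inp <- load_family_inputs(cfg)
  baseline <- fsp_baseline()
  parts <- lapply(names(inp$seqs), function(pid)
    partition_record(inp$seqs[[pid]],
                     inp$regions[inp$regions$id == pid, , drop = FALSE]))
  views <- list(full = vapply(parts, `[[`, character(1), "full"),
                ap2 = vapply(parts, `[[`, character(1), "ap2_only"),
                ap2_deleted = vapply(parts, `[[`, character(1), "ap2_deleted"))
  paths <- character(0)
  for (v in names(views)) {
    seqs <- views[[v]][nchar(views[[v]]) > 0]
    prof <- bootstrap_profile(seqs, baseline, n_boot = cfg$profile$n_boot,
                              ci_level = cfg$profile$ci_level,
                              seed = cfg$seed)
    p <- file.path(cfg$out_dir, paste0("profile_", v, ".tsv"))
    write_profile(prof, p)
    paths <- c(paths, p)
  }
  paths
}

stage_chcdf <- function(cfg) {
  inp <- load_family_inputs(cfg)
  pts <- phase_points(inp$seqs, inp$regions, inp$tracks,
                      window = cfg$chcdf$window,
                      a = cfg$chcdf$boundary_a, b = cfg$chcdf$boundary_b,
                      bins = cfg$chcdf$cdf_bins)
  p <- file.path(cfg$out_dir, "phase_space.tsv")
  utils::write.table(pts, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

stage_idaa <- function(cfg) {
  inp <- load_family_inputs(cfg)
  tab <- idaa_by_region(inp$seqs, inp$regions, inp$tracks,
                        threshold = cfg$idaa$threshold)
  p <- file.path(cfg$out_dir, "idaa.tsv")
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

stage_cast <- function(cfg) {
  inp <- load_family_inputs(cfg)
  masks <- cast_mask_all(inp$seqs, threshold = cfg$cast$threshold)
  p1 <- file.path(cfg$out_dir, "low_complexity_segments.tsv")
  write_segments(masks, p1)
  p2 <- file.path(cfg$out_dir, "lcaa.tsv")
  utils::write.table(lcaa_by_region(inp$seqs, inp$regions, masks), p2,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(cfg$out_dir, "masked.fasta")
  write_fasta(vapply(masks, `[[`, character(1), "masked"), p3)
  c(p1, p2, p3)
}

stage_morfs <- function(cfg) {
  inp <- load_family_inputs(cfg)
  m <- cfg$morfs
  cand <- dip_candidates_all(inp$tracks, inp$regions,
                             dip_threshold = m$dip_threshold,
                             context_threshold = m$context_threshold,
                             min_len = m$min_len, max_len = m$max_len,
                             context = m$context)
  p <- file.path(cfg$out_dir, "morf_candidates.tsv")
  write_morfs(cand, p)
  p
}

stage_conserve <- function(cfg) {
  inp <- load_family_inputs(cfg)
  cand <- read_external_morfs(
    req_file(file.path(cfg$out_dir, "morf_candidates.tsv")), inp$seqs,
    source = "dip")
  calls <- list()
  for (sg in unique(inp$subgroups)) {
    members <- names(inp$subgroups)[inp$subgroups == sg]
    aln_path <- file.path(cfg$dir, paste0("aln_", sg, ".fasta"))
    msa <- if (file.exists(aln_path)) read_alignment(aln_path) else
      stats::setNames(inp$seqs[members], members)
    aligned <- map_to_alignment(msa, cand[cand$id %in% members, , drop = FALSE],
                                inp$seqs)
    calls <- c(calls, call_conserved(
      msa, aligned, members, inp$regions, sg,
      min_occupancy = cfg$conserve$min_occupancy,
      min_overlap_cols = cfg$conserve$min_overlap_cols))
  }
  calls <- flag_exclusive(calls, threshold = cfg$conserve$exclusive_identity)
  p <- file.path(cfg$out_dir, "conserved_morfs.tsv")
  utils::write.table(conserved_table(calls), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p
}

stage_ptm <- function(cfg) {
  inp <- load_family_inputs(cfg)
  sites <- read_phospho_table(req_file(file.path(cfg$dir, "phospho.tsv")),
                              inp$seqs)
  p <- file.path(cfg$out_dir, "phospho_fractions.tsv")
  utils::write.table(phospho_summary(inp$seqs, inp$regions, sites), p,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

stage_tree <- function(cfg) {
  msa <- read_alignment(req_file(file.path(cfg$dir, "ap2_alignment.fasta")))
  tree <- bootstrap_support(msa, n_boot = cfg$tree$n_boot, seed = cfg$seed)
  p1 <- file.path(cfg$out_dir, "nj_tree.nwk")
  ape::write.tree(tree, p1)
  p2 <- file.path(cfg$out_dir, "tree_support.tsv")
  utils::write.table(support_flags(tree, cfg$tree$support_cutoff), p2,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  c(p1, p2)
}

stage_eval <- function(cfg) {
  truth <- read_truth(cfg$dir)
  inp <- load_family_inputs(cfg)
  cand <- read_external_morfs(
    req_file(file.path(cfg$out_dir, "morf_candidates.tsv")), inp$seqs,
    source = "dip")
  seg_tab <- utils::read.delim(
    req_file(file.path(cfg$out_dir, "low_complexity_segments.tsv")),
    stringsAsFactors = FALSE)
  lc_pred <- data.frame(id = seg_tab$id, start = seg_tab$start - 1L,
                        end = seg_tab$end, stringsAsFactors = FALSE)
  tree <- ape::read.tree(req_file(file.path(cfg$out_dir, "nj_tree.nwk")))
  truth$morfs <- as.data.frame(truth$morfs)
  truth$low_complexity <- as.data.frame(truth$low_complexity)
  metrics <- truth_eval(list(morfs = cand, low_complexity = lc_pred,
                             subgroups = inp$subgroups, tree = tree), truth)
  p <- file.path(cfg$out_dir, "eval_metrics.json")
  jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA)
  p
}

# manifest bookkeeping: package version, stage parameters, artifact md5s
update_manifest <- function(stage, cfg, paths) {
  mpath <- file.path(cfg$out_dir, "manifest.json")
  manifest <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = FALSE) else
    list(package = "idrscape",
         version = as.character(utils::packageVersion("idrscape")),
         stages = list())
  digests <- as.list(tools::md5sum(paths))
  names(digests) <- basename(paths)
  manifest$stages[[stage]] <- list(parameters = cfg[[stage]],
                                   seed = cfg$seed, artifacts = digests)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  mpath
}
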