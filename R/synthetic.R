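# Synthetic protein-family generator with machine-readable ground truth.
#
# Families emulate the architecture the analysis assumes: a folded,
# conserved ~58-residue AP2-like DNA-binding domain (order-promoting
# composition, unusually rich in W, A and R) flanked on both sides by
# intrinsically disordered regions (disorder-promoting composition,
# E-enriched and K-depleted), with short conserved interaction motifs
# (MoRFs) planted at homologous flank positions within each subgroup,
# homopolymeric low-complexity runs, state-dependent disorder-score
# emissions and a toy phosphosite predictor. Compositional contrasts are
# deliberately caricatured so that classification properties are
# deterministic at test sample sizes.

# default motif pool; patterns echo the recurring ERF motif classes
# (EAR-like, EDLL-like, LWSY-like, MCGGAI-like, basic and
# aromatic/acidic repeats)
default_motif_pool <- function() {
  c(EAR = "LDLDLNLPPP", EDLL = "EEDLLGDLLD", LWSY = "DMLWSYSLLE",
    MCGGAI = "MCGGAILADF", BASIC = "RKRKSRQRWL", AROM = "DWFDFDLFDA",
    ACID = "FDYDALFDVD", HYDRO = "ILVFAWLVIM")
}

#' Order-promoting domain composition
#'
#' Residue sampling fractions for the synthetic AP2-like domain:
#' hydrophobic-rich with an unusually high portion of W, A and R, so that
#' extracted domains land on the compact side of the charge-hydropathy
#' boundary.
#' @return Named numeric vector over the 20 canonical residues (sums to 1).
#' @export
composition_ordered <- function() {
  c(A = 0.16, C = 0.01, D = 0.03, E = 0.04, F = 0.07, G = 0.06, H = 0.02,
    I = 0.07, K = 0.02, L = 0.09, M = 0.02, N = 0.02, P = 0.01, Q = 0.02,
    R = 0.10, S = 0.03, T = 0.03, V = 0.09, W = 0.08, Y = 0.03)
}

#' Disorder-promoting flank composition
#'
#' Residue sampling fractions for the synthetic disordered flanks:
#' enriched in E, S, P, Q and G, depleted in hydrophobics and in K (the
#' K-depletion mirrors the unusual lysine deficit of disordered
#' transcription-regulatory regions).
#' @return Named numeric vector over the 20 canonical residues (sums to 1).
#' @export
composition_disordered <- function() {
  c(A = 0.08, C = 0.005, D = 0.06, E = 0.12, F = 0.01, G = 0.09, H = 0.03,
    I = 0.02, K = 0.02, L = 0.04, M = 0.01, N = 0.04, P = 0.10, Q = 0.08,
    R = 0.06, S = 0.12, T = 0.06, V = 0.03, W = 0.005, Y = 0.02)
}

#' Specification of a synthetic protein family
#'
#' Defaults define the reference study conditions used throughout the
#' test-suite: 4 subgroups of 6 members, a 58-residue domain, planted
#' 10-residue motifs (one exclusive N-side motif per subgroup; subgroups
#' 1 and 2 share their C-side motif, the rest have exclusive ones), a
#' 12-residue homopolymer low-complexity run per protein, and
#' Beta-distributed score emissions: ordered Beta(2, 8), disordered
#' Beta(8, 2), motif dips Beta(2, 8).
#'
#' @param n_subgroups Number of subgroups.
#' @param members_per_subgroup Members per subgroup.
#' @param ap2_length Domain length.
#' @param ap2_mut_rate Per-residue substitution rate member vs subgroup
#'   consensus.
#' @param subgroup_div_rate Per-residue divergence of each subgroup
#'   consensus from the family root.
#' @param flank_len_n,flank_len_c Min/max flank lengths (drawn once per
#'   subgroup so members stay alignable without gaps).
#' @param ap2_composition,flank_composition Sampling fractions.
#' @param motifs Data.frame with columns \code{subgroup}, \code{side}
#'   (\code{N}/\code{C}), \code{motif}, \code{name}; \code{NULL} builds
#'   the default plan.
#' @param lc_length Planted homopolymer run length.
#' @param beta_ordered,beta_disordered,beta_dip Beta shape pairs for score
#'   emission.
#' @param phospho_rates Named list of S/T/Y Bernoulli rates for
#'   \code{disordered} and \code{ap2} regions.
#' @param track_mode \code{"emitted"} (state-dependent Beta draws) or
#'   \code{"internal"} (scores computed from sequence with
#'   \code{\link{internal_track}}).
#' @param seed Mandatory integer seed; all outputs are deterministic
#'   given it.
#' @return A \code{family_spec} list.
#' @export
family_spec <- function(n_subgroups = 4L, members_per_subgroup = 6L,
                        ap2_length = 58L, ap2_mut_rate = 0.08,
                        subgroup_div_rate = 0.15,
                        flank_len_n = c(40L, 90L), flank_len_c = c(60L, 120L),
                        ap2_composition = composition_ordered(),
                        flank_composition = composition_disordered(),
                        motifs = NULL, lc_length = 12L,
                        beta_ordered = c(2, 8), beta_disordered = c(8, 2),
                        beta_dip = c(2, 8),
                        phospho_rates = list(
                          disordered = c(S = 0.25, T = 0.20, Y = 0.05),
                          ap2 = c(S = 0.05, T = 0.05, Y = 0.30)),
                        track_mode = c("emitted", "internal"),
                        seed = NULL) {
  if (is.null(seed)) stop("family_spec requires an explicit seed")
  stopifnot(abs(sum(ap2_composition) - 1) < 1e-6,
            abs(sum(flank_composition) - 1) < 1e-6,
            ap2_length > 0, members_per_subgroup >= 2)
  track_mode <- match.arg(track_mode)
  if (is.null(motifs)) motifs <- default_motif_plan(n_subgroups)
  structure(list(n_subgroups = n_subgroups,
                 members_per_subgroup = members_per_subgroup,
                 ap2_length = ap2_length, ap2_mut_rate = ap2_mut_rate,
                 subgroup_div_rate = subgroup_div_rate,
                 flank_len_n = flank_len_n, flank_len_c = flank_len_c,
                 ap2_composition = ap2_composition,
                 flank_composition = flank_composition,
                 motifs = motifs, lc_length = lc_length,
                 beta_ordered = beta_ordered,
                 beta_disordered = beta_disordered, beta_dip = beta_dip,
                 phospho_rates = phospho_rates, track_mode = track_mode,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# one exclusive N motif per subgroup; subgroups 1 and 2 share a C motif,
# the rest get exclusive C motifs
default_motif_plan <- function(n_subgroups) {
  pool <- default_motif_pool()
  if (2 * n_subgroups - 1 > length(pool))
    pool <- c(pool, stats::setNames(
      vapply(seq_len(2 * n_subgroups), function(i)
        paste(rev(strsplit(pool[[(i - 1) %% length(pool) + 1]], "")[[1]]),
              collapse = ""), character(1)),
      paste0("REV", seq_len(2 * n_subgroups))))
  rows <- list()
  for (g in seq_len(n_subgroups)) {
    rows[[length(rows) + 1L]] <- data.frame(
      subgroup = g, side = "N", motif = unname(pool[g]),
      name = names(pool)[g], stringsAsFactors = FALSE)
    ci <- if (g <= 2L) n_subgroups + 1L else n_subgroups + g - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      subgroup = g, side = "C", motif = unname(pool[ci]),
      name = names(pool)[ci], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

random_protein <- function(n, composition) {
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

mutate_seq <- function(sequence, rate, composition) {
  chars <- strsplit(sequence, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- sample(names(composition), sum(hit), replace = TRUE,
                         prob = composition)
  paste(chars, collapse = "")
}

# beta-strand/alpha-helix layout inside the domain, scaled to its length
ap2_sub_layout <- function(ap2_length) {
  f <- ap2_length / 58
  r <- function(x) as.integer(round(x * f))
  data.frame(label = c("BETA", "BETA", "BETA", "ALPHA"),
             start = c(r(4), r(17), r(28), r(40)),
             end = c(r(14), r(25), r(36), r(54)), stringsAsFactors = FALSE)
}

#' Generate a synthetic protein family with ground truth
#'
#' Builds sequences, region annotations, disorder-score tracks, planted
#' MoRF and low-complexity coordinates, phosphosite predictions, subgroup
#' assignments, per-subgroup alignments, a family domain alignment and
#' the generating tree — all deterministic given \code{spec$seed}. When
#' \code{dir} is given, every artifact is also written in the plain-text
#' formats the pipeline consumes.
#'
#' @param spec A \code{\link{family_spec}}.
#' @param dir Optional output directory.
#' @return List with components \code{seqs}, \code{regions},
#'   \code{tracks}, \code{morfs}, \code{phospho}, \code{subgroups},
#'   \code{alignments}, \code{ap2_alignment}, \code{tree} and
#'   \code{truth}.
#' @export
generate_family <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  out <- with_seed(spec$seed, generate_family_impl(spec))
  if (!is.null(dir)) write_family(out, dir)
  out
}

generate_family_impl <- function(spec) {
  root_ap2 <- random_protein(spec$ap2_length, spec$ap2_composition)
  layout <- ap2_sub_layout(spec$ap2_length)
  lc_residues <- c("S", "Q", "E", "G")
  seqs <- character(0); regions <- list(); tracks <- list()
  morf_truth <- list(); lc_truth <- list(); phospho <- list()
  subgroups <- character(0); alignments <- list()
  for (g in seq_len(spec$n_subgroups)) {
    sg <- sprintf("SG%d", g)
    consensus <- mutate_seq(root_ap2, spec$subgroup_div_rate,
                            spec$ap2_composition)
    n_len <- sample(spec$flank_len_n[1]:spec$flank_len_n[2], 1L)
    c_len <- sample(spec$flank_len_c[1]:spec$flank_len_c[2], 1L)
    plan <- spec$motifs[spec$motifs$subgroup == g, , drop = FALSE]
    lc_res <- lc_residues[(g - 1L) %% length(lc_residues) + 1L]
    member_ids <- character(0)
    for (m in seq_len(spec$members_per_subgroup)) {
      pid <- sprintf("sg%02d_m%02d", g, m)
      ap2_seq <- mutate_seq(consensus, spec$ap2_mut_rate, spec$ap2_composition)
      nf <- random_protein(n_len, spec$flank_composition)
      cf <- random_protein(c_len, spec$flank_composition)
      # plant motifs at homologous flank offsets
      motif_rows <- list()
      for (k in seq_len(nrow(plan))) {
        motif <- plan$motif[k]
        L <- nchar(motif)
        if (plan$side[k] == "N") {
          if (L > n_len) stop("motif longer than N flank")
          off <- floor(0.3 * n_len)
          substr(nf, off + 1L, off + L) <- motif
          abs_start <- off
        } else {
          if (L > c_len) stop("motif longer than C flank")
          off <- floor(0.4 * c_len)
          substr(cf, off + 1L, off + L) <- motif
          abs_start <- n_len + spec$ap2_length + off
        }
        motif_rows[[k]] <- data.frame(
          id = pid, start = abs_start, end = abs_start + L,
          side = plan$side[k], motif = plan$name[k], subgroup = sg,
          stringsAsFactors = FALSE)
      }
      # plant a homopolymer low-complexity run late in the C flank
      lc_off <- floor(0.75 * c_len)
      lc_end <- min(lc_off + spec$lc_length, c_len)
      substr(cf, lc_off + 1L, lc_end) <- strrep(lc_res, lc_end - lc_off)
      lc_truth[[length(lc_truth) + 1L]] <- data.frame(
        id = pid, start = n_len + spec$ap2_length + lc_off,
        end = n_len + spec$ap2_length + lc_end, residue = lc_res,
        stringsAsFactors = FALSE)
      seq_full <- paste0(nf, ap2_seq, cf)
      total <- nchar(seq_full)
      seqs[pid] <- seq_full
      subgroups[pid] <- sg
      member_ids <- c(member_ids, pid)
      reg <- rbind(
        data.frame(id = pid, label = "N_FLANK", start = 0L, end = n_len,
                   stringsAsFactors = FALSE),
        data.frame(id = pid, label = "AP2", start = n_len,
                   end = n_len + spec$ap2_length, stringsAsFactors = FALSE),
        data.frame(id = pid, label = layout$label,
                   start = n_len + layout$start, end = n_len + layout$end,
                   stringsAsFactors = FALSE),
        data.frame(id = pid, label = "C_FLANK",
                   start = n_len + spec$ap2_length, end = total,
                   stringsAsFactors = FALSE))
      regions[[pid]] <- reg
      morf_df <- do.call(rbind, motif_rows)
      morf_truth[[length(morf_truth) + 1L]] <- morf_df
      # score track: state-dependent Beta emissions
      if (spec$track_mode == "emitted") {
        state <- rep("dis", total)
        state[(n_len + 1L):(n_len + spec$ap2_length)] <- "ord"
        for (k in seq_len(nrow(morf_df)))
          state[(morf_df$start[k] + 1L):morf_df$end[k]] <- "dip"
        sc <- numeric(total)
        sc[state == "ord"] <- stats::rbeta(sum(state == "ord"),
                                           spec$beta_ordered[1], spec$beta_ordered[2])
        sc[state == "dis"] <- stats::rbeta(sum(state == "dis"),
                                           spec$beta_disordered[1], spec$beta_disordered[2])
        sc[state == "dip"] <- stats::rbeta(sum(state == "dip"),
                                           spec$beta_dip[1], spec$beta_dip[2])
      } else {
        sc <- as.numeric(internal_track(seq_full))
      }
      attr(sc, "source") <- "internal"
      tracks[[pid]] <- sc
      # toy phosphosite predictor: S/T followed by P always predicted,
      # otherwise Bernoulli per type and region
      chars <- strsplit(seq_full, "")[[1]]
      sty <- which(chars %in% c("S", "T", "Y"))
      if (length(sty) > 0L) {
        in_ap2 <- sty > n_len & sty <= n_len + spec$ap2_length
        rates <- ifelse(in_ap2,
                        vapply(chars[sty], function(r) spec$phospho_rates$ap2[[r]], numeric(1)),
                        vapply(chars[sty], function(r) spec$phospho_rates$disordered[[r]], numeric(1)))
        pred <- stats::runif(length(sty)) < rates
        sp_rule <- chars[sty] %in% c("S", "T") & sty < total &
          chars[pmin(sty + 1L, total)] == "P"
        phospho[[length(phospho) + 1L]] <- data.frame(
          id = pid, position = sty - 1L, residue = chars[sty],
          predicted = pred | sp_rule, score = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    # members of a subgroup share flank lengths, so they align without gaps
    alignments[[sg]] <- seqs[member_ids]
  }
  regions <- do.call(rbind, regions)
  rownames(regions) <- NULL
  morfs <- do.call(rbind, morf_truth); rownames(morfs) <- NULL
  lc <- do.call(rbind, lc_truth); rownames(lc) <- NULL
  phospho <- do.call(rbind, phospho); rownames(phospho) <- NULL
  ap2_alignment <- vapply(names(seqs), function(pid)
    partition_record(seqs[[pid]], regions[regions$id == pid, ])$ap2_only,
    character(1))
  tree <- generating_tree(subgroups)
  # exclusivity of each planted motif name: used by exactly one subgroup
  plan <- spec$motifs
  excl <- !(plan$name %in% plan$name[duplicated(plan$name)])
  names(excl) <- paste(plan$subgroup, plan$side, plan$name)
  truth <- list(morfs = morfs, low_complexity = lc, subgroups = subgroups,
                motif_plan = cbind(plan, exclusive = excl),
                tree = ape::write.tree(tree))
  list(seqs = seqs, regions = regions, tracks = tracks,
       morfs = morfs[, c("id", "start", "end")], phospho = phospho,
       subgroups = subgroups, alignments = alignments,
       ap2_alignment = ap2_alignment, tree = tree, truth = truth)
}

# star-within-subgroup generating topology
generating_tree <- function(subgroups) {
  clades <- vapply(unique(subgroups), function(g) {
    members <- names(subgroups)[subgroups == g]
    paste0("(", paste0(members, ":0.1", collapse = ","), "):0.5")
  }, character(1))
  ape::read.tree(text = paste0("(", paste(clades, collapse = ","), ");"))
}

#' Write a generated family to disk
#'
#' Emits exactly the plain-text formats the pipeline consumes: FASTA
#' sequences, region/track/MoRF/phosphosite/subgroup TSVs, per-subgroup
#' and domain alignments, the generating tree (newick) and the ground
#' truth (JSON).
#'
#' @param fam Result of \code{\link{generate_family}}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fam$seqs, file.path(dir, "sequences.fasta"))
  write_region_table(fam$regions, file.path(dir, "regions.tsv"))
  write_track(fam$tracks, fam$seqs, file.path(dir, "tracks.tsv"))
  write_morfs(cbind(fam$morfs, source = "planted"),
              file.path(dir, "morfs.tsv"))
  ph <- fam$phospho
  ph$position <- ph$position + 1L
  utils::write.table(ph, file.path(dir, "phospho.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_subgroups(fam$subgroups, file.path(dir, "subgroups.tsv"))
  for (sg in names(fam$alignments))
    write_fasta(fam$alignments[[sg]],
                file.path(dir, paste0("aln_", sg, ".fasta")))
  write_fasta(fam$ap2_alignment, file.path(dir, "ap2_alignment.fasta"))
  ape::write.tree(fam$tree, file.path(dir, "tree.nwk"))
  truth <- fam$truth
  truth$subgroups <- as.list(truth$subgroups)  # keep names in JSON
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a family's ground truth back from disk
#'
#' @param dir Directory written by \code{\link{write_family}}.
#' @return Truth list (morfs, low_complexity, subgroups, motif_plan,
#'   tree).
#' @export
read_truth <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$subgroups <- unlist(truth$subgroups)
  truth
}

# >= 50% reciprocal overlap between two half-open spans
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ov >= 0.5 * (e1 - s1) & ov >= 0.5 * (e2 - s2)
}

#' Recall and precision of predicted segments against planted truth
#'
#' A predicted segment matches a planted one when they share the same
#' protein and overlap reciprocally by at least 50%.
#'
#' @param predicted Data.frame with \code{id}, \code{start}, \code{end}.
#' @param truth Data.frame with \code{id}, \code{start}, \code{end}.
#' @return List with \code{recall}, \code{precision} (NA when there are
#'   no predictions), \code{n_truth}, \code{n_predicted}.
#' @export
segment_recovery <- function(predicted, truth) {
  matched_truth <- logical(nrow(truth))
  matched_pred <- logical(nrow(predicted))
  for (i in seq_len(nrow(truth))) {
    j <- which(predicted$id == truth$id[i] &
                 reciprocal_overlap(predicted$start, predicted$end,
                                    truth$start[i], truth$end[i]))
    if (length(j) > 0L) { matched_truth[i] <- TRUE; matched_pred[j] <- TRUE }
  }
  list(recall = if (nrow(truth) > 0L) mean(matched_truth) else NA_real_,
       precision = if (nrow(predicted) > 0L) mean(matched_pred) else NA_real_,
       n_truth = nrow(truth), n_predicted = nrow(predicted))
}

#' Evaluate pipeline output against generated ground truth
#'
#' Overlap-based matching (50% reciprocal) for MoRF and low-complexity
#' segments, exact-label accuracy for quadrants and subgroups, and
#' Robinson-Foulds topological distance for trees. Components of
#' \code{predictions} that are absent are skipped.
#'
#' @param predictions List with optional components \code{morfs} (segment
#'   data.frame), \code{low_complexity} (segment data.frame),
#'   \code{subgroups} (named vector), \code{quadrants} (named vector) and
#'   \code{tree} (\code{phylo}).
#' @param truth Truth list from \code{\link{generate_family}} or
#'   \code{\link{read_truth}}.
#' @param expected_quadrants Optional named vector of expected quadrant
#'   labels.
#' @return Named list of metric lists.
#' @export
truth_eval <- function(predictions, truth, expected_quadrants = NULL) {
  out <- list()
  if (!is.null(predictions$morfs)) {
    bad <- setdiff(unique(predictions$morfs$id), unique(truth$morfs$id))
    if (length(bad) > 0L)
      stop("predicted MoRFs reference unknown protein(s): ",
           paste(bad, collapse = ", "))
    out$morfs <- segment_recovery(predictions$morfs, truth$morfs)
  }
  if (!is.null(predictions$low_complexity))
    out$low_complexity <- segment_recovery(predictions$low_complexity,
                                           truth$low_complexity)
  if (!is.null(predictions$subgroups)) {
    ids <- intersect(names(predictions$subgroups), names(truth$subgroups))
    out$subgroups <- list(
      accuracy = mean(predictions$subgroups[ids] == truth$subgroups[ids]))
  }
  if (!is.null(predictions$quadrants) && !is.null(expected_quadrants)) {
    ids <- intersect(names(predictions$quadrants), names(expected_quadrants))
    out$quadrants <- list(
      accuracy = mean(predictions$quadrants[ids] == expected_quadrants[ids]))
  }
  if (!is.null(predictions$tree)) {
    ref <- ape::read.tree(text = truth$tree)
    out$tree <- list(rf_distance =
      as.numeric(ape::dist.topo(ape::unroot(predictions$tree),
                                ape::unroot(ref))))
  }
  out
}
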