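# Molecular recognition feature (MoRF) candidate detection, ingestion of
# external MoRF predictions, alignment mapping, and subgroup-level
# conserved-MoRF calling, naming and exclusivity flagging.
#
# MoRF segments are data.frames with columns id, start, end (0-based
# half-open residue coordinates), source and mean_score.

empty_morfs <- function() {
  data.frame(id = character(0), start = integer(0), end = integer(0),
             source = character(0), mean_score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Detect MoRF candidates as order-propensity dips in a disorder track
#'
#' A candidate is a maximal run of scores below \code{dip_threshold} whose
#' length lies within bounds, whose flanking context windows (width
#' \code{context}) have mean score at or above \code{context_threshold}
#' (one-sided at the sequence ends), and which does not overlap an AP2
#' span — in-domain MoRFs are taken from external predictions only. Dips
#' mirror the downward spikes of order propensity seen inside long
#' disordered regions, which tend to coincide with binding elements.
#'
#' @param scores Per-residue disorder scores for one protein.
#' @param regions Region data.frame rows for this protein (AP2 exclusion).
#' @param id Protein id recorded on the output rows.
#' @param dip_threshold Scores below this count as dip (default 0.5).
#' @param context_threshold Minimum mean score of the flanking context
#'   (default 0.5).
#' @param min_len,max_len Candidate length bounds (defaults 5 and 25).
#' @param context Context window width (default 10).
#' @return MoRF data.frame (possibly zero rows), source \code{"dip"}.
#' @export
dip_candidates <- function(scores, regions = NULL, id = NA_character_,
                           dip_threshold = 0.5, context_threshold = 0.5,
                           min_len = 5L, max_len = 25L, context = 10L) {
  n <- length(scores)
  below <- scores < dip_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  out <- empty_morfs()
  ap2 <- if (is.null(regions)) NULL else
    regions[regions$label == "AP2", , drop = FALSE]
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    len <- e - s
    if (len < min_len || len > max_len) next
    left <- if (s > 0L) scores[max(1L, s - context + 1L):s] else numeric(0)
    right <- if (e < n) scores[(e + 1L):min(n, e + context)] else numeric(0)
    ok_left <- length(left) == 0L || mean(left) >= context_threshold
    ok_right <- length(right) == 0L || mean(right) >= context_threshold
    if (length(left) == 0L && length(right) == 0L) next  # whole-sequence dip
    if (!(ok_left && ok_right)) next
    if (!is.null(ap2) && nrow(ap2) > 0L &&
        any(pmin(e, ap2$end) - pmax(s, ap2$start) > 0)) next
    out <- rbind(out, data.frame(id = id, start = s, end = e,
                                 source = "dip",
                                 mean_score = mean(scores[(s + 1L):e]),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Detect dip MoRF candidates for a set of proteins
#'
#' @param tracks Named list of score vectors.
#' @param regions Region data.frame.
#' @param ... Passed to \code{\link{dip_candidates}}.
#' @return Combined MoRF data.frame.
#' @export
dip_candidates_all <- function(tracks, regions, ...) {
  rows <- lapply(names(tracks), function(pid)
    dip_candidates(tracks[[pid]], regions[regions$id == pid, , drop = FALSE],
                   id = pid, ...))
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_morfs() else out
}

#' Read externally predicted MoRF segments
#'
#' Two schemas are supported. Span mode: columns \code{id}, \code{start},
#' \code{end} (1-based inclusive); overlapping or adjacent rows for the
#' same protein are merged. Score mode: columns \code{id},
#' \code{position}, \code{score}; runs of at least \code{min_len}
#' consecutive positions with score at or above \code{threshold} become
#' segments.
#'
#' @param path Path to the TSV file.
#' @param seqs Named sequences for span validation.
#' @param threshold Calling threshold for score mode (default 0.725).
#' @param min_len Minimum run length in score mode (default 5).
#' @param source Provenance label (default derived from the file name).
#' @return MoRF data.frame.
#' @export
read_external_morfs <- function(path, seqs, threshold = 0.725, min_len = 5L,
                                source = paste0("external:", basename(path))) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- empty_morfs()
  if (all(c("id", "start", "end") %in% names(tab))) {
    for (pid in unique(tab$id)) {
      sub <- tab[tab$id == pid, , drop = FALSE]
      if (!pid %in% names(seqs)) stop("MoRF table references unknown protein: ", pid)
      if (any(sub$start < 1L) || any(sub$end > nchar(seqs[[pid]])))
        stop("MoRF span outside sequence for: ", pid)
      iv <- merge_intervals(sub$start - 1L, sub$end)
      out <- rbind(out, data.frame(id = pid, start = iv$start, end = iv$end,
                                   source = source, mean_score = NA_real_,
                                   stringsAsFactors = FALSE))
    }
  } else if (all(c("id", "position", "score") %in% names(tab))) {
    for (pid in unique(tab$id)) {
      sub <- tab[tab$id == pid, , drop = FALSE]
      sub <- sub[order(sub$position), , drop = FALSE]
      pass <- sub$position[sub$score >= threshold]
      if (length(pass) == 0L) next
      breaks <- c(0L, which(diff(pass) != 1L), length(pass))
      for (j in seq_len(length(breaks) - 1L)) {
        run <- pass[(breaks[j] + 1L):breaks[j + 1L]]
        if (length(run) < min_len) next
        if (max(run) > nchar(seqs[[pid]]))
          stop("MoRF position outside sequence for: ", pid)
        out <- rbind(out, data.frame(
          id = pid, start = min(run) - 1L, end = max(run),
          source = source,
          mean_score = mean(sub$score[sub$position %in% run]),
          stringsAsFactors = FALSE))
      }
    }
  } else {
    stop("MoRF table must have columns id,start,end or id,position,score")
  }
  out
}

# merge overlapping or adjacent half-open intervals
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  rs <- integer(0); re <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i]) else {
      rs <- c(rs, ms); re <- c(re, me); ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(rs, ms), end = c(re, me))
}

#' Map residue coordinates to alignment columns
#'
#' Converts a 0-based half-open residue span of the ungapped sequence to
#' the corresponding half-open span of alignment columns through the gap
#' structure of the aligned sequence.
#'
#' @param aligned A single aligned sequence (with \code{-} gaps).
#' @param start,end Residue span (0-based half-open).
#' @return Integer vector \code{c(col_start, col_end)} (0-based
#'   half-open).
#' @export
residues_to_columns <- function(aligned, start, end) {
  chars <- strsplit(aligned, "")[[1]]
  res_cols <- which(chars != "-")  # 1-based columns of residues
  if (end > length(res_cols)) stop("residue span exceeds ungapped length")
  c(res_cols[start + 1L] - 1L, res_cols[end])
}

#' Map alignment columns back to residue coordinates
#'
#' Inverse of \code{\link{residues_to_columns}}: the residue span covered
#' by the given half-open column span (gap columns contribute nothing).
#'
#' @param aligned A single aligned sequence.
#' @param col_start,col_end Column span (0-based half-open).
#' @return Integer vector \code{c(start, end)} in residue coordinates.
#' @export
columns_to_residues <- function(aligned, col_start, col_end) {
  chars <- strsplit(aligned, "")[[1]]
  is_res <- chars != "-"
  before <- sum(is_res[seq_len(col_start)])
  inside <- sum(is_res[(col_start + 1L):col_end])
  c(before, before + inside)
}

#' Map MoRF segments to alignment-column coordinates
#'
#' @param msa Named aligned sequences; must contain every protein carrying
#'   a MoRF, and each ungapped sequence must equal the FASTA sequence.
#' @param morfs MoRF data.frame (residue coordinates).
#' @param seqs Optional named sequences for consistency validation.
#' @return The MoRF data.frame with added \code{col_start},
#'   \code{col_end}.
#' @export
map_to_alignment <- function(msa, morfs, seqs = NULL) {
  if (nrow(morfs) == 0L) {
    morfs$col_start <- integer(0); morfs$col_end <- integer(0)
    return(morfs)
  }
  missing <- setdiff(unique(morfs$id), names(msa))
  if (length(missing) > 0L)
    stop("alignment missing protein(s): ", paste(missing, collapse = ", "))
  if (!is.null(seqs)) {
    for (pid in unique(morfs$id)) {
      ungapped <- gsub("-", "", msa[[pid]])
      if (!identical(ungapped, unname(seqs[[pid]])))
        stop("aligned sequence mismatches FASTA for: ", pid)
    }
  }
  cols <- t(vapply(seq_len(nrow(morfs)), function(i)
    residues_to_columns(msa[[morfs$id[i]]], morfs$start[i], morfs$end[i]),
    integer(2)))
  morfs$col_start <- cols[, 1]
  morfs$col_end <- cols[, 2]
  morfs
}

#' Call conserved MoRFs within one subgroup
#'
#' Aligned MoRF spans are clustered by single linkage on column overlap
#' (at least \code{min_overlap_cols} shared columns joins two spans);
#' clusters whose occupancy — the fraction of subgroup members carrying an
#' overlapping MoRF — reaches \code{min_occupancy} are reported as
#' conserved. Each call is assigned a side relative to the AP2 domain
#' columns (N before, C after, AP2 overlapping), numbered
#' N-terminal-to-C-terminal within its side, and named
#' \code{"<subgroup> <side><index>"}. The consensus is the majority
#' residue per aligned column over covering members (ties and gap
#' majorities become \code{X}).
#'
#' @param msa Named aligned sequences of the subgroup members.
#' @param aligned_morfs MoRF data.frame with \code{col_start},
#'   \code{col_end} from \code{\link{map_to_alignment}}.
#' @param members Character vector of subgroup member ids (at least 2).
#' @param regions Region data.frame (AP2 spans, for side assignment).
#' @param subgroup_id Subgroup label used in names.
#' @param min_occupancy Minimum occupancy (default 0.75).
#' @param min_overlap_cols Minimum shared columns for linkage (default 5).
#' @return List of conserved-MoRF records; each has fields \code{name},
#'   \code{subgroup}, \code{side}, \code{col_start}, \code{col_end},
#'   \code{member_hits} (data.frame), \code{occupancy}, \code{consensus}
#'   and \code{exclusive} (NA until flagged).
#' @export
call_conserved <- function(msa, aligned_morfs, members, regions, subgroup_id,
                           min_occupancy = 0.75, min_overlap_cols = 5L) {
  if (length(members) < 2L) stop("subgroup must have at least 2 members")
  m <- aligned_morfs[aligned_morfs$id %in% members, , drop = FALSE]
  if (nrow(m) == 0L) return(list())
  m <- m[order(m$col_start, m$col_end, m$id), , drop = FALSE]
  # single-linkage components on column overlap
  comp <- seq_len(nrow(m))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
      if (comp[i] != comp[j] &&
          min(m$col_end[i], m$col_end[j]) - max(m$col_start[i], m$col_start[j]) >=
          min_overlap_cols) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  ap2_cols <- ap2_column_span(msa, regions, members)
  calls <- list()
  for (cid in unique(comp)) {
    hits <- m[comp == cid, , drop = FALSE]
    occ <- length(unique(hits$id)) / length(members)
    if (occ < min_occupancy) next
    span <- c(min(hits$col_start), max(hits$col_end))
    mid <- mean(span)
    side <- if (!is.null(ap2_cols) && mid >= ap2_cols[1] && mid < ap2_cols[2])
      "AP2" else if (!is.null(ap2_cols) && mid < ap2_cols[1]) "N" else
      if (!is.null(ap2_cols)) "C" else "N"
    calls[[length(calls) + 1L]] <- list(
      subgroup = subgroup_id, side = side,
      col_start = span[1], col_end = span[2],
      member_hits = hits[, c("id", "start", "end", "col_start", "col_end")],
      occupancy = occ,
      consensus = column_consensus(msa, hits),
      exclusive = NA)
  }
  # name within side, ordered by column position
  for (side in c("N", "AP2", "C")) {
    idx <- which(vapply(calls, function(x) x$side == side, logical(1)))
    idx <- idx[order(vapply(calls[idx], function(x) x$col_start, numeric(1)))]
    for (k in seq_along(idx))
      calls[[idx[k]]]$name <- paste0(subgroup_id, " ", side, k)
  }
  calls[order(vapply(calls, function(x) x$col_start, numeric(1)))]
}

# union AP2 column span over members (NULL when no AP2 annotations)
ap2_column_span <- function(msa, regions, members) {
  ap2 <- regions[regions$id %in% members & regions$label == "AP2", , drop = FALSE]
  if (nrow(ap2) == 0L) return(NULL)
  spans <- t(vapply(seq_len(nrow(ap2)), function(i)
    residues_to_columns(msa[[ap2$id[i]]], ap2$start[i], ap2$end[i]),
    integer(2)))
  c(min(spans[, 1]), max(spans[, 2]))
}

# majority residue per column over member hits covering the column
column_consensus <- function(msa, hits) {
  span <- c(min(hits$col_start), max(hits$col_end))
  cons <- character(0)
  for (col in (span[1] + 1L):span[2]) {  # 1-based column
    covering <- which(hits$col_start < col & hits$col_end >= col)
    if (length(covering) == 0L) next
    chars <- vapply(covering, function(i)
      substr(msa[[hits$id[i]]], col, col), character(1))
    tab <- sort(table(chars), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    cons <- c(cons, if (length(top) > 1L || top[1] == "-") "X" else top[1])
  }
  paste(cons, collapse = "")
}

#' Flag conserved MoRFs exclusive to their subgroup
#'
#' A conserved MoRF is exclusive when no other subgroup has a conserved
#' MoRF whose consensus matches it with identity at or above the
#' threshold under the best ungapped offset (identity over the shorter
#' consensus length).
#'
#' @param all_calls List of conserved-MoRF records across all subgroups.
#' @param threshold Identity threshold (default 0.6).
#' @return The list with \code{exclusive} flags set.
#' @export
flag_exclusive <- function(all_calls, threshold = 0.6) {
  for (i in seq_along(all_calls)) {
    others <- Filter(function(x) x$subgroup != all_calls[[i]]$subgroup, all_calls)
    sim <- vapply(others, function(x)
      consensus_identity(all_calls[[i]]$consensus, x$consensus), numeric(1))
    all_calls[[i]]$exclusive <- length(sim) == 0L || all(sim < threshold)
  }
  all_calls
}

# best ungapped-offset identity between two consensus strings, over the
# length of the shorter one; all overlapping offsets (including
# overhangs) are tried; X never matches
consensus_identity <- function(x, y) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  na <- length(a); nb <- length(b)
  if (na == 0L) return(0)
  best <- 0
  for (off in (1L - na):(nb - 1L)) {
    i <- seq_len(na)
    keep <- i + off >= 1L & i + off <= nb
    if (!any(keep)) next
    matches <- sum(a[keep] == b[i[keep] + off] & a[keep] != "X")
    best <- max(best, matches / na)
  }
  best
}

#' Conserved-MoRF summary table
#'
#' @param calls List of conserved-MoRF records.
#' @return Data.frame with columns \code{name}, \code{subgroup},
#'   \code{side}, \code{occupancy}, \code{consensus}, \code{exclusive}.
#' @export
conserved_table <- function(calls) {
  if (length(calls) == 0L)
    return(data.frame(name = character(0), subgroup = character(0),
                      side = character(0), occupancy = numeric(0),
                      consensus = character(0), exclusive = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(calls, function(x)
    data.frame(name = x$name, subgroup = x$subgroup, side = x$side,
               occupancy = x$occupancy, consensus = x$consensus,
               exclusive = x$exclusive, stringsAsFactors = FALSE)))
}

#' Expand conserved-MoRF calls into per-member hit segments
#'
#' @param calls List of conserved-MoRF records.
#' @return Data.frame with columns \code{id}, \code{start}, \code{end}
#'   (residue coordinates), \code{name}, \code{subgroup},
#'   \code{exclusive}.
#' @export
conserved_member_hits <- function(calls) {
  if (length(calls) == 0L)
    return(data.frame(id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      subgroup = character(0), exclusive = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(calls, function(x)
    data.frame(id = x$member_hits$id, start = x$member_hits$start,
               end = x$member_hits$end, name = x$name,
               subgroup = x$subgroup, exclusive = x$exclusive,
               stringsAsFactors = FALSE)))
}

#' Occupancy of AP2 sub-regions by MoRFs, per subgroup
#'
#' For each subgroup and each AP2 sub-region (the three beta strands in
#' N-to-C order and the alpha helix), the fraction of members with at
#' least one AP2-overlapping MoRF that also overlaps the sub-region.
#'
#' @param morfs MoRF data.frame (residue coordinates).
#' @param regions Region data.frame with BETA/ALPHA sub-annotations.
#' @param subgroups Named character vector mapping protein id to subgroup.
#' @return Data.frame with columns \code{subgroup}, \code{beta1},
#'   \code{beta2}, \code{beta3}, \code{alpha}.
#' @export
ap2_morf_layout <- function(morfs, regions, subgroups) {
  ids <- names(subgroups)
  no_sub <- vapply(ids, function(pid) {
    reg <- regions[regions$id == pid, , drop = FALSE]
    sum(reg$label == "BETA") < 3L || sum(reg$label == "ALPHA") < 1L
  }, logical(1))
  if (any(no_sub))
    stop("missing BETA/ALPHA sub-annotations for: ",
         paste(ids[no_sub], collapse = ", "))
  rows <- list()
  for (g in unique(subgroups)) {
    members <- ids[subgroups == g]
    hit <- matrix(FALSE, nrow = length(members), ncol = 4,
                  dimnames = list(members, c("beta1", "beta2", "beta3", "alpha")))
    for (pid in members) {
      reg <- regions[regions$id == pid, , drop = FALSE]
      betas <- reg[reg$label == "BETA", , drop = FALSE]
      betas <- betas[order(betas$start), , drop = FALSE]
      alpha <- reg[reg$label == "ALPHA", , drop = FALSE][1, ]
      subs <- rbind(betas[1:3, c("start", "end")], alpha[, c("start", "end")])
      m <- morfs[morfs$id == pid, , drop = FALSE]
      if (nrow(m) == 0L) next
      for (k in 1:4) {
        hit[pid, k] <- any(pmin(m$end, subs$end[k]) -
                             pmax(m$start, subs$start[k]) > 0)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subgroup = g, beta1 = mean(hit[, 1]), beta2 = mean(hit[, 2]),
      beta3 = mean(hit[, 3]), alpha = mean(hit[, 4]), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write MoRF segments to a TSV (1-based inclusive on disk)
#'
#' @param morfs MoRF data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_morfs <- function(morfs, path) {
  out <- data.frame(id = morfs$id, start = morfs$start + 1L, end = morfs$end,
                    source = morfs$source, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
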