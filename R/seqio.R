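# Sequence and region I/O, and partitioning of proteins into the AP2
# DNA-binding domain, its beta/alpha sub-spans, and the flanking regions.
#
# Coordinate convention: internal coordinates are 0-based half-open
# [start, end); on-disk region tables are 1-based inclusive. Conversion
# happens only at the I/O boundary.

#' The twenty canonical amino-acid one-letter codes
#'
#' Alphabetical ordering; used as the canonical residue axis for counts and
#' compositions. Non-canonical letters are mapped to \code{X} on input and
#' excluded from all composition denominators.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Recognised region labels
#'
#' \code{AP2} marks the DNA-binding domain span; \code{BETA} and
#' \code{ALPHA} mark secondary-structure sub-spans nested inside an AP2
#' span; \code{N_FLANK} and \code{C_FLANK} mark the disordered regions
#' outside the domain.
#' @export
REGION_LABELS <- c("AP2", "BETA", "ALPHA", "N_FLANK", "C_FLANK")

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and any letter outside the 20 canonical
#' amino-acid codes is replaced by \code{X} (with a warning naming the
#' affected records).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), seqs)
  if (any(bad)) {
    warning("non-canonical residues mapped to X in: ",
            paste(ids[bad], collapse = ", "))
    seqs <- vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      chars[!chars %in% c(AA20, "X")] <- "X"
      paste(chars, collapse = "")
    }, character(1))
    names(seqs) <- ids
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA: ", path)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a region annotation table
#'
#' The on-disk table is TSV with a header line and columns \code{id},
#' \code{label}, \code{start}, \code{end}; coordinates are 1-based
#' inclusive. Internally coordinates become 0-based half-open. BETA and
#' ALPHA spans must nest inside an AP2 span of the same protein.
#'
#' @param path Path to the TSV file.
#' @param seqs Optional named character vector of sequences; when supplied,
#'   spans are validated against sequence lengths.
#' @return A data.frame with columns \code{id}, \code{label}, \code{start},
#'   \code{end} (0-based half-open).
#' @export
read_region_table <- function(path, seqs = NULL) {
  if (!file.exists(path)) stop("region table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "label", "start", "end")
  if (!all(need %in% names(tab)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  bad_lab <- setdiff(unique(tab$label), REGION_LABELS)
  if (length(bad_lab) > 0L)
    stop("unknown region label(s): ", paste(bad_lab, collapse = ", "))
  if (any(tab$start > tab$end))
    stop("invalid span (start > end) in region table: ",
         paste(tab$id[tab$start > tab$end], collapse = ", "))
  if (any(tab$start < 1L)) stop("region table coordinates are 1-based; start < 1")
  regions <- data.frame(id = as.character(tab$id), label = tab$label,
                        start = as.integer(tab$start) - 1L,
                        end = as.integer(tab$end), stringsAsFactors = FALSE)
  validate_regions(regions, seqs)
  regions
}

#' Write a region annotation table
#'
#' Converts internal 0-based half-open coordinates back to the on-disk
#' 1-based inclusive convention; a round trip through
#' \code{read_region_table} is the identity.
#'
#' @param regions Region data.frame (internal coordinates).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_region_table <- function(regions, path) {
  out <- data.frame(id = regions$id, label = regions$label,
                    start = regions$start + 1L, end = regions$end,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate region annotations
#'
#' Checks the structural invariants: spans non-empty and within the
#' sequence, AP2 spans mutually non-overlapping, and BETA/ALPHA spans
#' nested inside an AP2 span of the same protein.
#'
#' @param regions Region data.frame (internal coordinates).
#' @param seqs Optional named sequences for length validation.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_regions <- function(regions, seqs = NULL) {
  if (any(regions$start >= regions$end))
    stop("empty or inverted region span for: ",
         paste(regions$id[regions$start >= regions$end], collapse = ", "))
  if (!is.null(seqs)) {
    len <- nchar(seqs)[regions$id]
    if (any(is.na(len)))
      stop("region table references unknown protein id(s): ",
           paste(unique(regions$id[is.na(len)]), collapse = ", "))
    if (any(regions$end > len))
      stop("region span exceeds sequence length for: ",
           paste(unique(regions$id[regions$end > len]), collapse = ", "))
  }
  for (pid in unique(regions$id)) {
    sub <- regions[regions$id == pid, , drop = FALSE]
    ap2 <- sub[sub$label == "AP2", , drop = FALSE]
    if (nrow(ap2) > 1L) {
      o <- order(ap2$start)
      if (any(ap2$start[o][-1L] < ap2$end[o][-nrow(ap2)]))
        stop("overlapping AP2 spans for: ", pid)
    }
    nest <- sub[sub$label %in% c("BETA", "ALPHA"), , drop = FALSE]
    if (nrow(nest) > 0L) {
      ok <- vapply(seq_len(nrow(nest)), function(i) {
        any(ap2$start <= nest$start[i] & nest$end[i] <= ap2$end)
      }, logical(1))
      if (!all(ok))
        stop("BETA/ALPHA span outside any AP2 span for: ", pid)
    }
  }
  invisible(TRUE)
}

#' Partition a protein into full, AP2-only and AP2-deleted views
#'
#' \code{ap2_only} concatenates the AP2 spans in order; \code{ap2_deleted}
#' is the sequence with those spans removed, so the two views together
#' conserve the residue multiset of the full sequence. A protein with no
#' AP2 annotation yields an empty \code{ap2_only} view.
#'
#' @param sequence A single protein sequence.
#' @param regions Region data.frame rows for this protein (internal
#'   coordinates); only rows labelled \code{AP2} are used.
#' @return List with character scalars \code{full}, \code{ap2_only},
#'   \code{ap2_deleted}.
#' @export
partition_record <- function(sequence, regions = NULL) {
  ap2 <- if (is.null(regions)) NULL else
    regions[regions$label == "AP2", , drop = FALSE]
  if (is.null(ap2) || nrow(ap2) == 0L)
    return(list(full = sequence, ap2_only = "", ap2_deleted = sequence))
  ap2 <- ap2[order(ap2$start), , drop = FALSE]
  chars <- strsplit(sequence, "")[[1]]
  in_ap2 <- rep(FALSE, length(chars))
  for (i in seq_len(nrow(ap2)))
    in_ap2[(ap2$start[i] + 1L):ap2$end[i]] <- TRUE
  list(full = sequence,
       ap2_only = paste(chars[in_ap2], collapse = ""),
       ap2_deleted = paste(chars[!in_ap2], collapse = ""))
}

#' Drop proteins carrying multiple AP2 domains
#'
#' Proteins annotated with more than one AP2 span are unusual (typically
#' tandem-domain outliers) and are removed from family-level analyses by
#' default, with a warning naming them.
#'
#' @param seqs Named sequences.
#' @param regions Region data.frame.
#' @return List with filtered \code{seqs} and \code{regions}.
#' @export
drop_multi_ap2 <- function(seqs, regions) {
  ap2 <- regions[regions$label == "AP2", , drop = FALSE]
  counts <- table(ap2$id)
  multi <- names(counts)[counts > 1L]
  if (length(multi) > 0L) {
    warning("dropping protein(s) with multiple AP2 domains: ",
            paste(multi, collapse = ", "))
    seqs <- seqs[!names(seqs) %in% multi]
    regions <- regions[!regions$id %in% multi, , drop = FALSE]
  }
  list(seqs = seqs, regions = regions)
}

#' Build a position weight model from example domain sequences
#'
#' Log-odds scores per column against a uniform background, with a
#' pseudocount; the hit threshold defaults to a fraction of the maximal
#' attainable score.
#'
#' @param domain_seqs Character vector of equal-length domain sequences.
#' @param pseudocount Added to every count (default 0.5).
#' @param threshold_frac Hit threshold as a fraction of the maximum score
#'   (default 0.7).
#' @return A list with \code{length}, \code{weights} (20 x L matrix, rows
#'   named by residue) and \code{threshold}.
#' @export
build_pwm <- function(domain_seqs, pseudocount = 0.5, threshold_frac = 0.7) {
  L <- unique(nchar(domain_seqs))
  if (length(L) != 1L) stop("domain sequences must have equal length")
  mat <- do.call(rbind, strsplit(domain_seqs, ""))
  weights <- vapply(seq_len(L), function(j) {
    counts <- table(factor(mat[, j], levels = AA20)) + pseudocount
    log2((counts / sum(counts)) / (1 / 20))
  }, numeric(20))
  rownames(weights) <- AA20
  max_score <- sum(apply(weights, 2, max))
  list(length = L, weights = weights, threshold = threshold_frac * max_score)
}

#' Scan a sequence for domain hits with a position weight model
#'
#' Scores every window; windows at or above the threshold are kept and
#' overlapping hits are resolved to the highest-scoring one (ties to the
#' leftmost). \code{X} residues contribute a score of 0.
#'
#' @param sequence A protein sequence.
#' @param pwm Model from \code{\link{build_pwm}}.
#' @return Region data.frame of AP2 annotations (possibly zero rows).
#' @export
scan_domain <- function(sequence, pwm) {
  n <- nchar(sequence)
  L <- pwm$length
  empty <- data.frame(id = character(0), label = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, AA20)  # NA for X
  scores <- vapply(0:(n - L), function(s) {
    ri <- idx[(s + 1L):(s + L)]
    keep <- !is.na(ri)
    if (!any(keep)) return(0)
    sum(pwm$weights[cbind(ri[keep], which(keep))])
  }, numeric(1))
  hit_start <- which(scores >= pwm$threshold) - 1L
  if (length(hit_start) == 0L) return(empty)
  # greedy resolution: highest score first, leftmost on ties
  ord <- order(-scores[hit_start + 1L], hit_start)
  kept <- integer(0)
  for (s in hit_start[ord]) {
    if (!any(abs(kept - s) < L)) kept <- c(kept, s)
  }
  kept <- sort(kept)
  data.frame(id = NA_character_, label = "AP2", start = kept,
             end = kept + L, stringsAsFactors = FALSE)
}
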