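# CAST-style iterative low-complexity detection and region-partitioned
# LCAA% statistics.
#
# The detector repeatedly aligns the sequence against each residue-type
# homopolymer via per-position substitution scores, finds the
# maximal-scoring contiguous segment (Kadane scan), and masks the dominant
# residue type within the best segment until no segment reaches the
# threshold.

#' The BLOSUM62 substitution matrix
#'
#' Fetched from Biostrings; used as the default scoring matrix for
#' low-complexity masking.
#' @return Integer matrix with residue row/column names.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# maximal-scoring contiguous segment (Kadane); ties broken to the
# leftmost maximal segment. Returns list(score, start, end) 0-based
# half-open, or score -Inf for empty input.
max_segment <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) return(list(score = -Inf, start = 0L, end = 0L))
  best <- -Inf; best_start <- 0L; best_end <- 0L
  cur <- 0; cur_start <- 0L
  for (i in seq_len(n)) {
    if (cur <= 0) { cur <- x[i]; cur_start <- i - 1L } else cur <- cur + x[i]
    if (cur > best) { best <- cur; best_start <- cur_start; best_end <- i }
  }
  list(score = best, start = best_start, end = best_end)
}

#' Iterative low-complexity masking of a protein sequence
#'
#' For each residue type the sequence is scored position-by-position
#' against an infinite homopolymer of that type using the substitution
#' matrix, and the maximal-scoring contiguous segment is found. While the
#' best (type, segment) score reaches the threshold, occurrences of that
#' type inside the segment are replaced by \code{X} and the segment is
#' recorded; the scan then repeats on the masked sequence. Ties are broken
#' deterministically: higher score, then leftmost start, then alphabetical
#' residue.
#'
#' @param sequence Protein sequence.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param threshold Minimum segment score (default 40).
#' @return List with \code{masked} (sequence with low-complexity residues
#'   as \code{X}) and \code{segments} (data.frame \code{start}, \code{end}
#'   0-based half-open, \code{residue}, \code{score}).
#' @export
cast_mask <- function(sequence, matrix = blosum62(), threshold = 40) {
  stopifnot(threshold > 0)
  empty_seg <- data.frame(start = integer(0), end = integer(0),
                          residue = character(0), score = numeric(0),
                          stringsAsFactors = FALSE)
  if (nchar(sequence) == 0L)
    return(list(masked = sequence, segments = empty_seg))
  chars <- strsplit(sequence, "")[[1]]
  segs <- empty_seg
  repeat {
    best <- NULL
    for (r in AA20) {
      sc <- matrix[chars, r]
      m <- max_segment(sc)
      if (m$score >= threshold) {
        if (is.null(best) ||
            m$score > best$score ||
            (m$score == best$score && (m$start < best$start ||
              (m$start == best$start && r < best$residue)))) {
          best <- list(score = m$score, start = m$start, end = m$end,
                       residue = r)
        }
      }
    }
    if (is.null(best)) break
    span <- (best$start + 1L):best$end
    chars[span][chars[span] == best$residue] <- "X"
    segs <- rbind(segs, data.frame(start = best$start, end = best$end,
                                   residue = best$residue, score = best$score,
                                   stringsAsFactors = FALSE))
  }
  list(masked = paste(chars, collapse = ""), segments = segs)
}

#' Low-complexity masking over a set of proteins
#'
#' @param seqs Named sequences.
#' @inheritParams cast_mask
#' @return Named list of \code{\link{cast_mask}} results.
#' @export
cast_mask_all <- function(seqs, matrix = blosum62(), threshold = 40) {
  lapply(seqs, cast_mask, matrix = matrix, threshold = threshold)
}

#' LCAA% by region class
#'
#' Percentage of low-complexity (masked) residues within each region
#' class: \code{full}, \code{beta} (union of BETA spans), \code{alpha}
#' (union of ALPHA spans) and \code{non_ap2} (complement of AP2 spans).
#' Masks must have been computed on the full-length sequences. A region
#' class absent for a protein is reported as \code{NA}, not 0.
#'
#' @param seqs Named full-length sequences.
#' @param regions Region data.frame.
#' @param masks Named list of \code{\link{cast_mask}} results.
#' @return Data.frame with columns \code{id}, \code{region_class},
#'   \code{lcaa_percent}.
#' @export
lcaa_by_region <- function(seqs, regions, masks) {
  rows <- list()
  for (pid in names(seqs)) {
    n <- nchar(seqs[[pid]])
    orig <- strsplit(seqs[[pid]], "")[[1]]
    masked <- strsplit(masks[[pid]]$masked, "")[[1]]
    is_lc <- masked == "X" & orig != "X"
    reg <- regions[regions$id == pid, , drop = FALSE]
    class_masks <- list(
      full = rep(TRUE, n),
      beta = region_mask(n, reg[reg$label == "BETA", , drop = FALSE]),
      alpha = region_mask(n, reg[reg$label == "ALPHA", , drop = FALSE]),
      non_ap2 = !region_mask(n, reg[reg$label == "AP2", , drop = FALSE]))
    for (cls in names(class_masks)) {
      m <- class_masks[[cls]]
      pct <- if (!any(m)) NA_real_ else 100 * sum(is_lc & m) / sum(m)
      rows[[length(rows) + 1L]] <- data.frame(
        id = pid, region_class = cls, lcaa_percent = pct,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write low-complexity segments to a TSV
#'
#' @param masks Named list of \code{\link{cast_mask}} results.
#' @param path Output path (columns id, start, end, residue, score;
#'   1-based inclusive coordinates on disk).
#' @return Invisibly, `path`.
#' @export
write_segments <- function(masks, path) {
  rows <- lapply(names(masks), function(pid) {
    s <- masks[[pid]]$segments
    if (nrow(s) == 0L) return(NULL)
    data.frame(id = pid, start = s$start + 1L, end = s$end,
               residue = s$residue, score = s$score, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(id = character(0), start = integer(0), end = integer(0),
               residue = character(0), score = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
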