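# Per-residue disorder tracks, the charge-hydropathy (CH) and cumulative
# distribution function (CDF) binary classifiers, the combined CH-CDF
# phase space, and IDAA% statistics.

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# per-residue Kyte-Doolittle values rescaled to [0,1] via (h + 4.5)/9;
# X counts as neutral (0.5)
kd_profile <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  h <- KD_SCALE[chars]
  h[is.na(h)] <- 0
  unname((h + 4.5) / 9)
}

# centered moving average with window truncated at the sequence ends
smooth_centered <- function(x, window) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- length(x)
  if (window == 1L || n == 1L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Mean normalized Kyte-Doolittle hydropathy
#'
#' Per-residue Kyte-Doolittle values are rescaled to [0,1] via
#' (h + 4.5)/9, smoothed with a centered window (truncated at the ends)
#' and averaged.
#'
#' @param sequence Protein sequence.
#' @param window Odd smoothing window (default 5).
#' @return Mean hydropathy in [0, 1].
#' @export
kd_hydropathy <- function(sequence, window = 5L) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  window <- min(window, nchar(sequence))
  if (window %% 2L == 0L) window <- window - 1L
  mean(smooth_centered(kd_profile(sequence), window))
}

#' Mean absolute net charge per residue
#'
#' |(#K + #R) - (#D + #E)| / length. Histidine is treated as neutral by
#' default; set \code{his_charge} to count it as positive.
#'
#' @param sequence Protein sequence.
#' @param his_charge Charge assigned to histidine (default 0).
#' @return Mean net charge in [0, 1].
#' @export
mean_net_charge <- function(sequence, his_charge = 0) {
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  pos <- sum(chars %in% c("K", "R")) + his_charge * sum(chars == "H")
  neg <- sum(chars %in% c("D", "E"))
  abs(pos - neg) / n
}

#' Signed distance to the charge-hydropathy boundary line
#'
#' The boundary <R> = a <H> - b separates disordered (above) from compact
#' (below) proteins. The raw vertical distance <R> - (a <H> - b) is
#' returned by default (positive = disordered side); the perpendicular
#' distance divides by sqrt(1 + a^2).
#'
#' @param h Mean normalized hydropathy.
#' @param r Mean absolute net charge.
#' @param a,b Boundary constants (defaults 2.785 and 1.151).
#' @param perpendicular Return the perpendicular distance instead of raw.
#' @return Signed distance (positive = disordered side of the line).
#' @export
ch_distance <- function(h, r, a = 2.785, b = 1.151, perpendicular = FALSE) {
  d <- r - (a * h - b)
  if (perpendicular) d / sqrt(1 + a^2) else d
}

#' Charge-hydropathy point for one sequence
#'
#' @inheritParams kd_hydropathy
#' @inheritParams ch_distance
#' @return List with \code{mean_hydropathy}, \code{mean_net_charge} and
#'   \code{ch_distance} (raw).
#' @export
ch_point <- function(sequence, window = 5L, a = 2.785, b = 1.151) {
  h <- kd_hydropathy(sequence, window)
  r <- mean_net_charge(sequence)
  list(mean_hydropathy = h, mean_net_charge = r,
       ch_distance = ch_distance(h, r, a, b))
}

#' Windowed charge/hydropathy stand-in disorder track
#'
#' A per-residue disorder propensity computed from local composition:
#' score = 0.5 - k (a H_w - b - R_w), clamped to [0, 1], where H_w and R_w
#' are the windowed mean normalized hydropathy and windowed absolute net
#' charge around each position. High-charge, low-hydropathy neighbourhoods
#' score above 0.5. This is a self-contained propensity track for running
#' the pipeline end to end; externally predicted tracks are first-class
#' via \code{\link{read_track}} and take precedence when supplied.
#'
#' @param sequence Protein sequence.
#' @param window Odd window (default 21).
#' @param k Gain applied to the boundary offset (default 0.5).
#' @param a,b Charge-hydropathy boundary constants.
#' @return Numeric vector of per-residue scores in [0, 1] with attribute
#'   \code{source = "internal"}.
#' @export
internal_track <- function(sequence, window = 21L, k = 0.5,
                           a = 2.785, b = 1.151) {
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  w <- min(window, n)
  if (w %% 2L == 0L) w <- w - 1L
  hw <- smooth_centered(kd_profile(sequence), w)
  chars <- strsplit(sequence, "")[[1]]
  q <- numeric(n)
  q[chars %in% c("K", "R")] <- 1
  q[chars %in% c("D", "E")] <- -1
  rw <- abs(smooth_centered(q, w))
  scores <- 0.5 - k * (a * hw - b - rw)
  scores <- pmin(pmax(scores, 0), 1)
  attr(scores, "source") <- "internal"
  scores
}

#' Read per-residue disorder score tracks
#'
#' TSV with columns \code{id}, \code{position} (1-based), \code{residue},
#' \code{score}. Each protein must be covered by consecutive positions
#' 1..length with residues matching the sequence; scores outside [0, 1]
#' are clamped with a warning.
#'
#' @param path Path to the TSV file.
#' @param seqs Named sequences to validate against.
#' @param source Provenance label stored on each track (default the file
#'   name).
#' @return Named list of numeric score vectors, one per protein.
#' @export
read_track <- function(path, seqs, source = paste0("external:", basename(path))) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "position", "residue", "score")
  if (!all(need %in% names(tab)))
    stop("track table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (pid in unique(tab$id)) {
    sub <- tab[tab$id == pid, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    if (!pid %in% names(seqs)) stop("track references unknown protein: ", pid)
    n <- nchar(seqs[[pid]])
    if (!identical(as.integer(sub$position), seq_len(n)))
      stop("track positions for ", pid, " are not consecutive 1..", n)
    chars <- strsplit(seqs[[pid]], "")[[1]]
    if (!all(sub$residue == chars))
      stop("track residue column mismatches sequence for: ", pid)
    sc <- as.numeric(sub$score)
    if (any(sc < 0 | sc > 1)) {
      warning("scores outside [0,1] clamped for: ", pid)
      sc <- pmin(pmax(sc, 0), 1)
    }
    attr(sc, "source") <- source
    out[[pid]] <- sc
  }
  out
}

#' Write per-residue disorder score tracks
#'
#' @param tracks Named list of score vectors.
#' @param seqs Named sequences (for the residue column).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_track <- function(tracks, seqs, path) {
  rows <- lapply(names(tracks), function(pid) {
    data.frame(id = pid, position = seq_along(tracks[[pid]]),
               residue = strsplit(seqs[[pid]], "")[[1]],
               score = as.numeric(tracks[[pid]]), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default CDF score bins
#'
#' Nine evaluation points 0.1 to 0.9 in steps of 0.1.
#' @return Numeric vector of bins.
#' @export
cdf_bins <- function() seq(0.1, 0.9, by = 0.1)

#' Default CDF boundary points
#'
#' The midpoint between the cumulative distributions of the package's
#' ordered (Beta(2, 8)) and disordered (Beta(8, 2)) score emission models,
#' evaluated at the CDF bins. Replace with
#' \code{\link{calibrate_cdf_boundary}} output or predictor-specific
#' points when external tracks are used.
#'
#' @param bins CDF bins (default \code{\link{cdf_bins}}).
#' @return Numeric vector of boundary CDF values, one per bin.
#' @export
cdf_default_boundary <- function(bins = cdf_bins()) {
  (stats::pbeta(bins, 2, 8) + stats::pbeta(bins, 8, 2)) / 2
}

#' Calibrate CDF boundary points from reference track sets
#'
#' Fits each boundary point as the midpoint between the mean CDF curves of
#' an ordered and a disordered reference set.
#'
#' @param ordered_tracks,disordered_tracks Lists of score vectors.
#' @param bins CDF bins.
#' @return Numeric vector of boundary CDF values.
#' @export
calibrate_cdf_boundary <- function(ordered_tracks, disordered_tracks,
                                   bins = cdf_bins()) {
  mean_curve <- function(tracks) {
    rowMeans(vapply(tracks, function(t)
      vapply(bins, function(b) mean(t <= b), numeric(1)), numeric(length(bins))))
  }
  (mean_curve(ordered_tracks) + mean_curve(disordered_tracks)) / 2
}

#' Cumulative distribution function curve of a disorder track
#'
#' The value at bin b is the fraction of residues with score <= b; the CDF
#' distance is the mean signed vertical offset from the boundary points
#' (positive = ordered side, since ordered tracks accumulate low scores
#' fast).
#'
#' @param scores Per-residue disorder scores.
#' @param bins Strictly increasing bins in (0, 1).
#' @param boundary Boundary CDF values, one per bin (default
#'   \code{\link{cdf_default_boundary}}).
#' @return List with \code{bins}, \code{cdf_values} and
#'   \code{cdf_distance}.
#' @export
cdf_curve <- function(scores, bins = cdf_bins(),
                      boundary = cdf_default_boundary(bins)) {
  if (length(scores) == 0L) stop("empty track")
  stopifnot(all(diff(bins) > 0), all(bins > 0 & bins < 1),
            length(boundary) == length(bins))
  values <- vapply(bins, function(b) mean(scores <= b), numeric(1))
  list(bins = bins, cdf_values = values,
       cdf_distance = mean(values - boundary))
}

#' CH-CDF phase-space quadrant of one protein
#'
#' The x axis is the CDF distance (positive = ordered by CDF) and the y
#' axis the CH distance (positive = disordered by CH). Quadrants follow
#' the binary-classifier agreement semantics: Q1 (upper-right) disordered
#' by CH but ordered by CDF; Q2 (lower-right) ordered by both; Q3
#' (lower-left) disordered by CDF but compact by CH; Q4 (upper-left)
#' disordered by both. A zero on either axis resolves toward the ordered
#' call (cdf >= 0 counts as ordered by CDF, ch <= 0 as ordered by CH).
#'
#' @param ch_distance Signed CH boundary distance.
#' @param cdf_distance Signed CDF boundary distance.
#' @return One of \code{"Q1"}, \code{"Q2"}, \code{"Q3"}, \code{"Q4"}.
#' @export
chcdf_quadrant <- function(ch_distance, cdf_distance) {
  cdf_ordered <- cdf_distance >= 0
  ch_disordered <- ch_distance > 0
  ifelse(cdf_ordered,
         ifelse(ch_disordered, "Q1", "Q2"),
         ifelse(ch_disordered, "Q4", "Q3"))
}

#' Phase-space points for a set of proteins and region views
#'
#' Computes, per protein and per view (\code{full}, \code{ap2},
#' \code{ap2_deleted}), the CH distance from the sequence view and the CDF
#' distance from the matching slice of the disorder track, plus the
#' quadrant label.
#'
#' @param seqs Named sequences.
#' @param regions Region data.frame.
#' @param tracks Named list of per-residue scores (full-length).
#' @param views Which region views to include.
#' @param window Hydropathy smoothing window.
#' @param a,b CH boundary constants.
#' @param bins,boundary CDF bins and boundary.
#' @return Data.frame with columns \code{id}, \code{region_class},
#'   \code{ch_distance}, \code{cdf_distance}, \code{quadrant}.
#' @export
phase_points <- function(seqs, regions, tracks,
                         views = c("full", "ap2", "ap2_deleted"),
                         window = 5L, a = 2.785, b = 1.151,
                         bins = cdf_bins(), boundary = cdf_default_boundary(bins)) {
  rows <- list()
  for (pid in names(seqs)) {
    reg <- regions[regions$id == pid, , drop = FALSE]
    part <- partition_record(seqs[[pid]], reg)
    sc <- tracks[[pid]]
    ap2_mask <- region_mask(nchar(seqs[[pid]]), reg[reg$label == "AP2", , drop = FALSE])
    slices <- list(full = list(seq = part$full, sc = sc),
                   ap2 = list(seq = part$ap2_only, sc = sc[ap2_mask]),
                   ap2_deleted = list(seq = part$ap2_deleted, sc = sc[!ap2_mask]))
    for (v in views) {
      sl <- slices[[v]]
      if (nchar(sl$seq) == 0L) next
      chd <- ch_distance(kd_hydropathy(sl$seq, window), mean_net_charge(sl$seq), a, b)
      cdfd <- cdf_curve(sl$sc, bins, boundary)$cdf_distance
      rows[[length(rows) + 1L]] <- data.frame(
        id = pid, region_class = v, ch_distance = chd, cdf_distance = cdfd,
        quadrant = chcdf_quadrant(chd, cdfd), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# logical mask of positions covered by the given region rows
region_mask <- function(n, regions) {
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(regions)))
    mask[(regions$start[i] + 1L):regions$end[i]] <- TRUE
  mask
}

#' Percentage of residues predicted disordered (IDAA%)
#'
#' 100 x (number of scores at or above the threshold) / track length.
#'
#' @param scores Per-residue disorder scores.
#' @param threshold Disorder call threshold in (0, 1) (default 0.5).
#' @return Percentage in [0, 100].
#' @export
idaa_fraction <- function(scores, threshold = 0.5) {
  if (length(scores) == 0L) stop("empty track")
  stopifnot(threshold > 0, threshold < 1)
  100 * mean(scores >= threshold)
}

#' Compositional disorder-promoting residue percentage
#'
#' An alternative, sequence-only reading of IDAA%: the percentage of
#' residues belonging to the disorder-promoting set
#' (A, R, G, Q, S, P, E, K).
#'
#' @param sequence Protein sequence.
#' @return Percentage in [0, 100].
#' @export
idaa_compositional <- function(sequence) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  100 * mean(chars %in% c("A", "R", "G", "Q", "S", "P", "E", "K"))
}

#' IDAA% summary per protein and region view
#'
#' @inheritParams phase_points
#' @param threshold Disorder call threshold.
#' @return Data.frame with columns \code{id}, \code{region_class},
#'   \code{idaa_percent}.
#' @export
idaa_by_region <- function(seqs, regions, tracks, threshold = 0.5) {
  rows <- list()
  for (pid in names(seqs)) {
    reg <- regions[regions$id == pid, , drop = FALSE]
    sc <- tracks[[pid]]
    ap2_mask <- region_mask(length(sc), reg[reg$label == "AP2", , drop = FALSE])
    for (v in c("full", "ap2", "ap2_deleted")) {
      sl <- switch(v, full = sc, ap2 = sc[ap2_mask], ap2_deleted = sc[!ap2_mask])
      if (length(sl) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        id = pid, region_class = v, idaa_percent = idaa_fraction(sl, threshold),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
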