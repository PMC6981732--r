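# Phosphosite fraction statistics by residue type and region class from
# ingested site-prediction tables.

#' Read a phosphosite prediction table
#'
#' TSV with columns \code{id}, \code{position} (1-based), \code{residue}
#' (S, T or Y), \code{predicted} (logical or 0/1) and optionally
#' \code{score}. Residues are validated against the sequences and
#' positions must be unique per protein.
#'
#' @param path Path to the TSV file.
#' @param seqs Named sequences.
#' @return Data.frame with \code{position} converted to 0-based.
#' @export
read_phospho_table <- function(path, seqs) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "position", "residue", "predicted")
  if (!all(need %in% names(tab)))
    stop("phospho table must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$residue %in% c("S", "T", "Y")))
    stop("phospho residue column must be S, T or Y")
  for (pid in unique(tab$id)) {
    sub <- tab[tab$id == pid, , drop = FALSE]
    if (!pid %in% names(seqs)) stop("phospho table references unknown protein: ", pid)
    if (anyDuplicated(sub$position)) stop("duplicate positions for: ", pid)
    chars <- strsplit(seqs[[pid]], "")[[1]]
    if (any(sub$position < 1L | sub$position > length(chars)))
      stop("position outside sequence for: ", pid)
    if (!all(chars[sub$position] == sub$residue))
      stop("phospho residue mismatches sequence for: ", pid)
  }
  data.frame(id = as.character(tab$id), position = as.integer(tab$position) - 1L,
             residue = tab$residue, predicted = as.logical(tab$predicted),
             score = if ("score" %in% names(tab)) tab$score else NA_real_,
             stringsAsFactors = FALSE)
}

#' Fraction of predicted phosphorylation by residue type and region
#'
#' For each residue type in \{S, T, Y\} the statistic is 100 x (predicted
#' sites of that type in the region) / (residues of that type in the
#' region); the combined column pools the three types. A type with zero
#' residues in the region is reported as \code{NA}, not 0.
#'
#' @param seqs Named sequences.
#' @param regions Region data.frame (AP2 spans used for partitioning).
#' @param sites Phosphosite data.frame from
#'   \code{\link{read_phospho_table}} (0-based positions).
#' @param region_class One of \code{"full"}, \code{"ap2"},
#'   \code{"non_ap2"}.
#' @return One-row data.frame with columns \code{region_class}, \code{S},
#'   \code{T}, \code{Y}, \code{all}, plus count columns
#'   \code{n_sites_*}/\code{n_res_*} for auditability.
#' @export
phospho_fractions <- function(seqs, regions, sites,
                              region_class = c("full", "ap2", "non_ap2")) {
  region_class <- match.arg(region_class)
  n_sites <- c(S = 0, T = 0, Y = 0)
  n_res <- c(S = 0, T = 0, Y = 0)
  for (pid in names(seqs)) {
    n <- nchar(seqs[[pid]])
    reg <- regions[regions$id == pid, , drop = FALSE]
    ap2 <- region_mask(n, reg[reg$label == "AP2", , drop = FALSE])
    in_class <- switch(region_class, full = rep(TRUE, n), ap2 = ap2,
                       non_ap2 = !ap2)
    chars <- strsplit(seqs[[pid]], "")[[1]]
    for (t in c("S", "T", "Y")) {
      n_res[t] <- n_res[t] + sum(chars == t & in_class)
      sub <- sites[sites$id == pid & sites$residue == t & sites$predicted, , drop = FALSE]
      if (nrow(sub) > 0L)
        n_sites[t] <- n_sites[t] + sum(in_class[sub$position + 1L])
    }
  }
  frac <- ifelse(n_res > 0, 100 * n_sites / n_res, NA_real_)
  all_frac <- if (sum(n_res) > 0) 100 * sum(n_sites) / sum(n_res) else NA_real_
  data.frame(region_class = region_class,
             S = frac[["S"]], T = frac[["T"]], Y = frac[["Y"]], all = all_frac,
             n_sites_S = n_sites[["S"]], n_sites_T = n_sites[["T"]],
             n_sites_Y = n_sites[["Y"]],
             n_res_S = n_res[["S"]], n_res_T = n_res[["T"]],
             n_res_Y = n_res[["Y"]], stringsAsFactors = FALSE)
}

#' Phosphosite fraction summary over all region classes
#'
#' @inheritParams phospho_fractions
#' @return Data.frame with one row per region class (\code{ap2},
#'   \code{non_ap2}, \code{full}).
#' @export
phospho_summary <- function(seqs, regions, sites) {
  do.call(rbind, lapply(c("ap2", "non_ap2", "full"), function(cls)
    phospho_fractions(seqs, regions, sites, cls)))
}
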