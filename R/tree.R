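# Neighbour-joining subgroup tree from a domain alignment: p-distances,
# a lightweight NJ agglomerator with deterministic tie-breaking, and
# column-resampling bootstrap support.

#' Read an aligned FASTA file
#'
#' Unlike \code{\link{read_fasta}}, gap characters (\code{-}) are
#' preserved; sequences are upper-cased and must share one aligned
#' length.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("alignment file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate ids in alignment")
  aln <- toupper(as.character(set))
  names(aln) <- ids
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must have equal length")
  aln
}

#' Pairwise p-distance matrix from an alignment
#'
#' For each pair, mismatches divided by the number of shared non-gap
#' columns; a pair with no shared columns is an error.
#'
#' @param msa Named aligned sequences (at least 2, equal length).
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id.
#' @export
p_distance <- function(msa) {
  if (length(msa) < 2L) stop("p_distance needs at least 2 sequences")
  if (length(unique(nchar(msa))) != 1L)
    stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(msa, ""))
  rownames(mat) <- names(msa)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  gap <- mat == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- !gap[i, ] & !gap[j, ]
    ns <- sum(shared)
    if (ns == 0L)
      stop("no shared non-gap columns between ", names(msa)[i], " and ",
           names(msa)[j])
    d[i, j] <- d[j, i] <- sum(mat[i, shared] != mat[j, shared]) / ns
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with deterministic tie-breaking (on
#' equal Q values the pair with the lexicographically lowest label pair
#' is joined; merged nodes carry their smallest constituent label).
#' Negative branch lengths are clamped to 0 with the deficit moved to the
#' sibling branch, preserving the joined pair's distance.
#'
#' @param d Symmetric distance matrix with labelled rows (n >= 3).
#' @return An unrooted \code{ape::phylo} tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (is.data.frame(d)) d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix must have labels")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 taxa")
  dm <- d
  frag <- rownames(dm)          # newick fragment per active node
  key <- rownames(dm)           # smallest constituent label, for ties
  while (nrow(dm) > 3L) {
    n <- nrow(dm)
    r <- rowSums(dm)
    Q <- (n - 2) * dm - outer(r, r, "+")
    diag(Q) <- Inf
    minq <- min(Q)
    cand <- which(Q - minq < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    kk <- vapply(seq_len(nrow(cand)), function(t) {
      pair <- sort(c(key[cand[t, 1]], key[cand[t, 2]]))
      paste(pair, collapse = "\r")
    }, character(1))
    pick <- cand[order(kk)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    dij <- dm[i, j]
    bi <- 0.5 * dij + (r[i] - r[j]) / (2 * (n - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj - bi; bi <- 0 }
    if (bj < 0) { bi <- bi - bj; bj <- 0 }
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    newkey <- min(key[i], key[j])
    dnew <- 0.5 * (dm[i, ] + dm[j, ] - dij)
    keep <- setdiff(seq_len(n), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    rownames(dm2) <- colnames(dm2) <- key
    dm <- dm2
  }
  b1 <- max(0, (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2)
  b2 <- max(0, (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2)
  b3 <- max(0, (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], b1, frag[2], b2, frag[3], b3)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for the neighbour-joining tree of an alignment
#'
#' Alignment columns are resampled with replacement \code{n_boot} times;
#' each replicate is rebuilt with \code{\link{p_distance}} +
#' \code{\link{nj_tree}}, and the support of every internal split of the
#' full-data tree is the percentage of replicates containing it
#' (bipartition comparison, rooting ignored). Deterministic given the
#' seed.
#'
#' @param msa Named aligned sequences.
#' @param n_boot Number of replicates (default 100).
#' @param seed Integer seed.
#' @return The full-data \code{phylo} tree with per-internal-node support
#'   percentages in \code{node.label}.
#' @export
bootstrap_support <- function(msa, n_boot = 100L, seed = 1L) {
  stopifnot(n_boot >= 1L)
  L <- unique(nchar(msa))
  if (length(L) != 1L || L < 2L) stop("alignment must have >= 2 columns")
  main <- nj_tree(p_distance(msa))
  mat <- do.call(rbind, strsplit(msa, ""))
  rownames(mat) <- names(msa)
  bs <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_msa <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      nj_tree(p_distance(rep_msa))
    })
  })
  counts <- ape::prop.clades(main, bs, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- as.character(round(100 * counts / n_boot, 1))
  main
}

#' Flag well-supported splits
#'
#' Reports each internal node's bootstrap support with a flag marking
#' supports above the cutoff (conventionally rendered as an asterisk).
#'
#' @param tree A \code{phylo} tree with support percentages in
#'   \code{node.label}.
#' @param cutoff Support cutoff (default 70).
#' @return Data.frame with columns \code{node}, \code{support},
#'   \code{flagged}.
#' @export
support_flags <- function(tree, cutoff = 70) {
  sup <- suppressWarnings(as.numeric(tree$node.label))
  data.frame(node = ape::Ntip(tree) + seq_along(sup), support = sup,
             flagged = !is.na(sup) & sup > cutoff)
}

#' Read a subgroup assignment table
#'
#' TSV with columns \code{id} and \code{subgroup}; each protein must be
#' assigned exactly once.
#'
#' @param path Path to the TSV file.
#' @return Named character vector (id -> subgroup).
#' @export
read_subgroups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "subgroup") %in% names(tab)))
    stop("subgroup table must have columns id, subgroup")
  if (anyDuplicated(tab$id))
    stop("protein assigned to multiple subgroups: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  stats::setNames(as.character(tab$subgroup), tab$id)
}

#' Write a subgroup assignment table
#'
#' @param subgroups Named character vector (id -> subgroup).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_subgroups <- function(subgroups, path) {
  utils::write.table(
    data.frame(id = names(subgroups), subgroup = unname(subgroups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
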