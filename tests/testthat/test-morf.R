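test_that("dip candidates are bounded, context-gated runs below threshold", {
  step <- c(rep(0.8, 30), rep(0.3, 10), rep(0.8, 30))
  d <- dip_candidates(step, id = "p")
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end), c(30L, 40L))

  short <- c(rep(0.8, 30), rep(0.3, 3), rep(0.8, 30))
  expect_equal(nrow(dip_candidates(short, id = "p")), 0L)

  # dip at the sequence start with one-sided context is accepted
  edge <- c(rep(0.3, 8), rep(0.8, 30))
  d2 <- dip_candidates(edge, id = "p")
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$start, 0L)

  # low context rejects the dip
  lowctx <- c(rep(0.4, 30), rep(0.3, 10), rep(0.4, 30))
  expect_equal(nrow(dip_candidates(lowctx, id = "p")), 0L)

  # dips overlapping an AP2 span are suppressed
  reg <- data.frame(id = "p", label = "AP2", start = 28L, end = 45L)
  expect_equal(nrow(dip_candidates(step, reg, id = "p")), 0L)
})

test_that("external MoRF tables convert coordinates and merge overlaps", {
  seqs <- c(p1 = strrep("A", 40))
  p <- write_tmp(c("id\tstart\tend", "p1\t12\t20"))
  m <- read_external_morfs(p, seqs)
  expect_equal(c(m$start, m$end), c(11L, 20L))

  p2 <- write_tmp(c("id\tstart\tend", "p1\t5\t12", "p1\t10\t18"))
  m2 <- read_external_morfs(p2, seqs)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(4L, 18L))

  p3 <- write_tmp(c("id\tstart\tend", "p1\t30\t50"))
  expect_error(read_external_morfs(p3, seqs), "outside")

  # score mode: six consecutive passing positions become one segment
  rows <- sprintf("p1\t%d\t%.3f", 1:40, c(rep(0.1, 10), rep(0.8, 6), rep(0.1, 24)))
  p4 <- write_tmp(c("id\tposition\tscore", rows))
  m4 <- read_external_morfs(p4, seqs, threshold = 0.725)
  expect_equal(nrow(m4), 1L)
  expect_equal(c(m4$start, m4$end), c(10L, 16L))
})

test_that("residue/column mapping passes through gaps and inverts", {
  # aligned "A-CD": residues 1..3 of "ACD"; segment [1,3) maps to cols [2,4)
  expect_equal(residues_to_columns("A-CD", 1L, 3L), c(2L, 4L))
  expect_equal(columns_to_residues("A-CD", 2L, 4L), c(1L, 3L))
  # whole ungapped sequence covers the full span
  expect_equal(residues_to_columns("A-CD", 0L, 3L), c(0L, 4L))
  # round trip over random gap structures
  set.seed(41)
  for (i in 1:10) {
    chars <- sample(c(AA20, "-"), 30, replace = TRUE, prob = c(rep(1, 20), 6))
    if (sum(chars != "-") < 5) next
    aln <- paste(chars, collapse = "")
    n_res <- sum(chars != "-")
    st <- sample(0:(n_res - 2), 1)
    en <- sample((st + 1):n_res, 1)
    cols <- residues_to_columns(aln, st, en)
    expect_equal(columns_to_residues(aln, cols[1], cols[2]), c(st, en))
  }
  expect_error(map_to_alignment(c(x = "A-CD"),
                                data.frame(id = "y", start = 0L, end = 1L)),
               "missing")
  expect_error(map_to_alignment(c(x = "A-CD"),
                                data.frame(id = "x", start = 0L, end = 1L),
                                seqs = c(x = "ACDE")), "mismatch")
})

test_that("conserved calls require occupancy and name by side and order", {
  # six members, ungapped alignment; motif planted at the same offset in
  # 6/6 (N side) and in 3/6 only (C side)
  set.seed(55)
  make_member <- function(full_n, full_c, ap2) {
    nf <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
    cf <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
    if (full_n) substr(nf, 11, 20) <- "LDLDLNLPPP"
    if (full_c) substr(cf, 16, 25) <- "EEDLLGDLLD"
    paste0(nf, ap2, cf)
  }
  ap2 <- paste(sample(AA20, 58, replace = TRUE), collapse = "")
  ids <- sprintf("m%d", 1:6)
  msa <- setNames(vapply(1:6, function(i)
    make_member(TRUE, i <= 3, ap2), character(1)), ids)
  regions <- data.frame(id = ids, label = "AP2", start = 40L, end = 98L)
  morfs <- rbind(
    data.frame(id = ids, start = 10L, end = 20L),
    data.frame(id = ids[1:3], start = 113L, end = 123L))
  aligned <- map_to_alignment(msa, morfs)
  calls <- call_conserved(msa, aligned, ids, regions, "IIIc")
  expect_length(calls, 1L)  # 3/6 fails the 0.75 occupancy default
  expect_equal(calls[[1]]$name, "IIIc N1")
  expect_equal(calls[[1]]$occupancy, 1.0)
  expect_equal(calls[[1]]$consensus, "LDLDLNLPPP")
  # occupancy recomputes from member hits
  expect_equal(length(unique(calls[[1]]$member_hits$id)) / 6,
               calls[[1]]$occupancy)

  # lowering the occupancy floor admits the C-side cluster, named C1
  calls2 <- call_conserved(msa, aligned, ids, regions, "IIIc",
                           min_occupancy = 0.5)
  expect_length(calls2, 2L)
  expect_setequal(vapply(calls2, `[[`, character(1), "name"),
                  c("IIIc N1", "IIIc C1"))

  # permutation invariance in member order
  perm <- sample(ids)
  calls3 <- call_conserved(msa[perm], aligned, perm, regions, "IIIc")
  expect_equal(conserved_table(calls3)[, c("name", "occupancy", "consensus")],
               conserved_table(calls)[, c("name", "occupancy", "consensus")])

  expect_error(call_conserved(msa, aligned, ids[1], regions, "IIIc"),
               "at least 2")
})

test_that("naming indices are consecutive and increase along the sequence", {
  fam <- default_family()
  calls <- call_family_conserved(fam)
  tab <- conserved_table(calls)
  for (sg in unique(tab$subgroup)) for (side in c("N", "C")) {
    sub <- tab[tab$subgroup == sg & tab$side == side, , drop = FALSE]
    if (nrow(sub) == 0) next
    idx <- as.integer(sub("^.* [NC]", "", sub$name))
    expect_equal(sort(idx), seq_along(idx))
  }
})

test_that("exclusivity reflects consensus sharing across subgroups", {
  mk <- function(subgroup, consensus) {
    list(subgroup = subgroup, side = "N", col_start = 0, col_end = 10,
         member_hits = data.frame(), occupancy = 1,
         consensus = consensus, exclusive = NA, name = paste(subgroup, "N1"))
  }
  # identical motif in two subgroups: neither exclusive
  calls <- flag_exclusive(list(mk("A", "LDLDLNLPPP"), mk("B", "LDLDLNLPPP"),
                               mk("C", "EEDLLGDLLD")))
  excl <- vapply(calls, `[[`, logical(1), "exclusive")
  expect_equal(excl, c(FALSE, FALSE, TRUE))
  # a single subgroup is vacuously exclusive
  solo <- flag_exclusive(list(mk("A", "LDLDLNLPPP")))
  expect_true(solo[[1]]$exclusive)
  # planted family: shared C motif of subgroups 1 and 2 is not exclusive
  fam <- default_family()
  tab <- conserved_table(flag_exclusive(call_family_conserved(fam)))
  shared <- tab[tab$subgroup %in% c("SG1", "SG2") & tab$side == "C", ]
  expect_true(all(!shared$exclusive))
  own <- tab[tab$side == "N", ]
  expect_true(all(own$exclusive))
})

test_that("AP2 sub-region occupancy distinguishes strand and helix binding", {
  ids <- sprintf("m%d", 1:4)
  reg <- do.call(rbind, lapply(ids, function(pid)
    data.frame(id = pid,
               label = c("AP2", "BETA", "BETA", "BETA", "ALPHA"),
               start = c(40L, 44L, 57L, 68L, 80L),
               end = c(98L, 54L, 65L, 76L, 94L), stringsAsFactors = FALSE)))
  subgroups <- setNames(rep("G1", 4), ids)
  # MoRFs covering only the first two strands
  m <- data.frame(id = ids, start = 44L, end = 65L)
  lay <- ap2_morf_layout(m, reg, subgroups)
  expect_equal(lay$beta1, 1.0)
  expect_equal(lay$beta2, 1.0)
  expect_equal(lay$alpha, 0.0)
  # MoRFs spanning the whole domain cover all four sub-regions
  m2 <- data.frame(id = ids, start = 40L, end = 98L)
  lay2 <- ap2_morf_layout(m2, reg, subgroups)
  expect_equal(unlist(lay2[, c("beta1", "beta2", "beta3", "alpha")]),
               c(beta1 = 1, beta2 = 1, beta3 = 1, alpha = 1))
  # no AP2 MoRFs at all: all four occupancies are zero
  m3 <- data.frame(id = ids, start = 0L, end = 10L)
  lay3 <- ap2_morf_layout(m3, reg, subgroups)
  expect_equal(unlist(lay3[, c("beta1", "beta2", "beta3", "alpha")]),
               c(beta1 = 0, beta2 = 0, beta3 = 0, alpha = 0))
  # missing sub-annotations are an error naming the proteins
  reg_bad <- reg[reg$label != "ALPHA", ]
  expect_error(ap2_morf_layout(m, reg_bad, subgroups), "m1")
})
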