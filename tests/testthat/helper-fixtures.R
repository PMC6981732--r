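# shared fixtures built in code at test time

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tmp_fasta <- function(...) write_tmp(c(...), ext = ".fasta")

# a tiny region table in on-disk (1-based inclusive) convention
region_lines <- function(rows) {
  c("id\tlabel\tstart\tend", vapply(rows, paste, character(1), collapse = "\t"))
}

# small cached default family so expensive tests share one instance
default_family <- local({
  fam <- NULL
  function(seed = 11L) {
    if (is.null(fam)) fam <<- generate_family(family_spec(seed = seed))
    fam
  }
})

# two clades with many fixed differences and no shared homoplasy
clean_clade_alignment <- function() {
  set.seed(83)
  base <- sample(AA20, 60, replace = TRUE)
  base2 <- base
  flip <- 1:30
  base2[flip] <- vapply(base2[flip], function(r) sample(setdiff(AA20, r), 1),
                        character(1))
  mk <- function(base, i) {
    s <- base
    s[50 + i] <- sample(setdiff(AA20, s[50 + i]), 1)  # unique private change
    paste(s, collapse = "")
  }
  c(setNames(vapply(1:5, function(i) mk(base, i), character(1)),
             paste0("a", 1:5)),
    setNames(vapply(1:5, function(i) mk(base2, i), character(1)),
             paste0("b", 1:5)))
}

# run conserved-MoRF calling over every subgroup of a generated family
call_family_conserved <- function(fam, ...) {
  cand <- dip_candidates_all(fam$tracks, fam$regions)
  calls <- list()
  for (sg in unique(fam$subgroups)) {
    members <- names(fam$subgroups)[fam$subgroups == sg]
    msa <- fam$alignments[[sg]]
    aligned <- map_to_alignment(msa, cand[cand$id %in% members, , drop = FALSE],
                                fam$seqs)
    calls <- c(calls, call_conserved(msa, aligned, members, fam$regions, sg, ...))
  }
  flag_exclusive(calls)
}
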