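test_that("FASTA parsing normalises case and non-canonical residues", {
  p <- tmp_fasta(">p1", "MKV")
  expect_identical(read_fasta(p), c(p1 = "MKV"))

  p <- tmp_fasta(">p1", "mkv")
  expect_identical(unname(read_fasta(p)["p1"]), "MKV")

  p <- tmp_fasta(">p1", "MKB")
  expect_warning(seqs <- read_fasta(p), "non-canonical")
  expect_identical(unname(seqs["p1"]), "MKX")

  expect_error(read_fasta(tmp_fasta(">p1", "MKV", ">p1", "AAA")), "duplicate")
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(read_fasta(empty))
})

test_that("FASTA write/read round trip preserves records", {
  seqs <- c(a = "MKVLW", b = "ACDEFGH")
  p <- tempfile(fileext = ".fasta")
  write_fasta(seqs, p)
  expect_identical(read_fasta(p), seqs)
})

test_that("region tables convert 1-based inclusive to internal half-open", {
  p <- write_tmp(region_lines(list(c("p1", "AP2", 10, 68))))
  reg <- read_region_table(p)
  expect_equal(reg$start, 9L)
  expect_equal(reg$end, 68L)

  expect_error(read_region_table(
    write_tmp(region_lines(list(c("p1", "AP2", 5, 3))))), "start > end")
  expect_error(read_region_table(
    write_tmp(region_lines(list(c("p1", "DOMAIN", 1, 5))))), "unknown")
  # BETA must nest inside an AP2 span
  expect_error(read_region_table(
    write_tmp(region_lines(list(c("p1", "BETA", 1, 5))))), "BETA/ALPHA")
})

test_that("region table round trip is the identity", {
  reg <- data.frame(id = c("p1", "p1"), label = c("AP2", "BETA"),
                    start = c(9L, 12L), end = c(68L, 20L),
                    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_region_table(reg, p)
  expect_equal(read_region_table(p), reg)
})

test_that("partition splits AP2 from flanks and conserves residues", {
  seq100 <- strrep("A", 40)
  set.seed(1)
  seq100 <- paste0(paste(sample(AA20, 100, replace = TRUE), collapse = ""))
  reg <- data.frame(id = "p", label = "AP2", start = 40L, end = 98L)
  part <- partition_record(seq100, reg)
  expect_equal(nchar(part$ap2_only), 58L)
  expect_equal(nchar(part$ap2_deleted), 42L)
  # residue multiset conservation
  count <- function(s) table(factor(strsplit(s, "")[[1]], levels = AA20))
  expect_equal(count(part$full),
               count(paste0(part$ap2_only, part$ap2_deleted)))

  expect_equal(partition_record(seq100, NULL)$ap2_only, "")
  whole <- data.frame(id = "p", label = "AP2", start = 0L, end = 100L)
  expect_equal(partition_record(seq100, whole)$ap2_deleted, "")
})

test_that("multi-AP2 proteins are dropped with a warning", {
  seqs <- c(a = strrep("A", 30), b = strrep("C", 30))
  reg <- data.frame(id = c("a", "a", "b"), label = "AP2",
                    start = c(0L, 10L, 0L), end = c(5L, 20L, 10L))
  expect_warning(out <- drop_multi_ap2(seqs, reg), "multiple AP2")
  expect_identical(names(out$seqs), "b")
})

test_that("PWM scan finds planted domains and respects the threshold", {
  set.seed(42)
  consensus <- paste(sample(AA20, 20, replace = TRUE,
                            prob = composition_ordered()), collapse = "")
  # small training set around the consensus
  train <- vapply(1:8, function(i) {
    chars <- strsplit(consensus, "")[[1]]
    mut <- sample(20, 2)
    chars[mut] <- sample(AA20, 2, replace = TRUE)
    paste(chars, collapse = "")
  }, character(1))
  pwm <- build_pwm(train)
  flank <- function(n) paste(sample(AA20, n, replace = TRUE,
                                    prob = composition_disordered()),
                             collapse = "")
  seq1 <- paste0(flank(40), consensus, flank(30))
  hits <- scan_domain(seq1, pwm)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 40L)

  # brute-force oracle: no window of a random disordered sequence passes
  rnd <- flank(200)
  chars <- strsplit(rnd, "")[[1]]
  brute <- vapply(0:(200 - pwm$length), function(s) {
    sum(pwm$weights[cbind(match(chars[(s + 1):(s + pwm$length)], AA20),
                          1:pwm$length)])
  }, numeric(1))
  expect_true(all(brute < pwm$threshold))
  expect_equal(nrow(scan_domain(rnd, pwm)), 0L)

  # two planted copies give two non-overlapping hits
  seq2 <- paste0(flank(30), consensus, flank(25), consensus, flank(20))
  hits2 <- scan_domain(seq2, pwm)
  expect_equal(nrow(hits2), 2L)
  expect_true(all(diff(sort(hits2$start)) >= pwm$length))

  # sequence shorter than the model yields no hits
  expect_equal(nrow(scan_domain("MKV", pwm)), 0L)
})
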