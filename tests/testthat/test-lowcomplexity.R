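# brute-force O(n^2) maximal-segment oracle
max_segment_oracle <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  best <- -Inf; bs <- 0L; be <- 0L
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    s <- cs[j + 1] - cs[i + 1]
    if (s > best) { best <- s; bs <- i; be <- j }
  }
  list(score = best, start = bs, end = be)
}

test_that("homopolymer masking follows the closed-form threshold rule", {
  m <- blosum62()
  # Q10 scores 10 x 5 = 50 >= 40: fully masked
  res <- cast_mask(strrep("Q", 10))
  expect_equal(nrow(res$segments), 1L)
  expect_equal(res$segments$score, 50)
  expect_equal(res$segments$start, 0L)
  expect_equal(res$segments$end, 10L)
  expect_equal(res$masked, strrep("X", 10))
  # Q7 scores 35 < 40: untouched
  res7 <- cast_mask(strrep("Q", 7))
  expect_equal(nrow(res7$segments), 0L)
  expect_equal(res7$masked, strrep("Q", 7))
  # all 20 homopolymers: masked iff length * self-score >= threshold
  for (r in AA20) {
    s <- m[r, r]
    len_below <- max(1L, ceiling(40 / s) - 1L)
    len_at <- ceiling(40 / s)
    expect_equal(nrow(cast_mask(strrep(r, len_below))$segments), 0L)
    expect_gte(nrow(cast_mask(strrep(r, len_at))$segments), 1L)
  }
})

test_that("linear-scan segment search agrees with the quadratic oracle", {
  m <- blosum62()
  set.seed(19)
  for (i in 1:40) {
    s <- paste(sample(AA20, 60, replace = TRUE), collapse = "")
    chars <- strsplit(s, "")[[1]]
    for (r in sample(AA20, 3)) {
      sc <- m[chars, r]
      fast <- idrscape:::max_segment(sc)
      slow <- max_segment_oracle(sc)
      expect_equal(fast$score, slow$score)
    }
  }
})

test_that("masking is idempotent and monotone in the threshold", {
  set.seed(23)
  seqs <- c(vapply(1:5, function(i)
    paste(sample(AA20, 150, replace = TRUE,
                 prob = composition_disordered()), collapse = ""),
    character(1)),
    paste0(strrep("A", 20), strrep("S", 15), strrep("A", 20)))
  for (s in seqs) {
    r1 <- cast_mask(s)
    r2 <- cast_mask(r1$masked)
    expect_equal(r2$masked, r1$masked)
    expect_equal(nrow(r2$segments), 0L)
    # masked fraction non-increasing as the threshold rises
    fracs <- vapply(c(30, 40, 60), function(t) {
      masked <- cast_mask(s, threshold = t)$masked
      mean(strsplit(masked, "")[[1]] == "X")
    }, numeric(1))
    expect_true(all(diff(fracs) <= 0))
  }
})

test_that("uniform-random sequences carry little low complexity", {
  set.seed(7)
  s <- paste(sample(AA20, 300, replace = TRUE), collapse = "")
  res <- cast_mask(s)
  expect_lt(mean(strsplit(res$masked, "")[[1]] == "X"), 0.05)
})

test_that("masking replaces only the dominant residue within the segment", {
  s <- paste0("MKV", strrep("Q", 5), "A", strrep("Q", 5), "MKV")
  res <- cast_mask(s)
  expect_equal(nrow(res$segments), 1L)
  expect_equal(res$segments$residue, "Q")
  # the interior A survives; flanking MKV survives
  expect_true(grepl("A", res$masked))
  expect_true(startsWith(res$masked, "MKV"))
})

test_that("LCAA% is partitioned by region class", {
  # mask covering only the N flank leaves beta/alpha at zero
  varied <- paste(rep(AA20, length.out = 30), collapse = "")
  seqs <- c(p = paste0(strrep("S", 12), varied, strrep("G", 8)))
  reg <- data.frame(id = "p",
                    label = c("N_FLANK", "AP2", "BETA", "ALPHA", "C_FLANK"),
                    start = c(0L, 12L, 14L, 30L, 42L),
                    end = c(12L, 42L, 22L, 40L, 50L), stringsAsFactors = FALSE)
  masks <- cast_mask_all(seqs)
  lc <- lcaa_by_region(seqs, reg, masks)
  expect_equal(lc$lcaa_percent[lc$region_class == "beta"], 0)
  expect_equal(lc$lcaa_percent[lc$region_class == "alpha"], 0)
  expect_gt(lc$lcaa_percent[lc$region_class == "non_ap2"], 0)

  # a fully masked protein reports 100 everywhere
  seqs2 <- c(q = strrep("Q", 50))
  reg2 <- reg; reg2$id <- "q"
  lc2 <- lcaa_by_region(seqs2, reg2, cast_mask_all(seqs2))
  expect_true(all(lc2$lcaa_percent == 100))

  # absent region class reports NA, not 0
  seqs3 <- c(r = strrep("Q", 50))
  reg3 <- data.frame(id = "r", label = "AP2", start = 0L, end = 50L)
  lc3 <- lcaa_by_region(seqs3, reg3, cast_mask_all(seqs3))
  expect_true(is.na(lc3$lcaa_percent[lc3$region_class == "beta"]))
})

test_that("planted homopolymer flank runs outscore the domain in LCAA%", {
  fam <- default_family()
  masks <- cast_mask_all(fam$seqs[1:6])
  lc <- lcaa_by_region(fam$seqs[1:6], fam$regions, masks)
  nonap2 <- lc$lcaa_percent[lc$region_class == "non_ap2"]
  beta <- lc$lcaa_percent[lc$region_class == "beta"]
  expect_gt(mean(nonap2), mean(beta))
})
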