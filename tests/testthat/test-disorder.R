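test_that("Kyte-Doolittle hydropathy is rescaled to [0,1]", {
  # KD(I) = 4.5 rescales to 1; KD(R) = -4.5 rescales to 0
  expect_equal(kd_hydropathy("IIIII", 5), 1.0)
  expect_equal(kd_hydropathy("RRRRR", 5), 0.0)
  # smoothing a homopolymer is window-invariant
  expect_equal(kd_hydropathy("AAAAAAA", 1), kd_hydropathy("AAAAAAA", 7))
  expect_error(kd_hydropathy(""), "empty")
})

test_that("mean net charge counts K/R against D/E", {
  expect_equal(mean_net_charge("EEEEK"), 0.6)
  expect_equal(mean_net_charge("KRDE"), 0.0)
  expect_equal(mean_net_charge("AAAA"), 0.0)
  # histidine neutral by default, charged on request
  expect_equal(mean_net_charge("HHHH"), 0.0)
  expect_equal(mean_net_charge("HHHH", his_charge = 1), 1.0)
})

test_that("CH distance is the signed offset from the boundary line", {
  expect_equal(ch_distance(0.5, 0.3), 0.3 - (2.785 * 0.5 - 1.151))
  expect_equal(ch_distance(0.5, 0.3), 0.0585)
  # a point on the line has zero distance
  h <- 0.6
  expect_equal(ch_distance(h, 2.785 * h - 1.151), 0)
  expect_equal(ch_distance(1.0, 0.0), -1.634)
  # perpendicular distance is the raw distance shrunk by the line norm
  expect_equal(ch_distance(0.5, 0.3, perpendicular = TRUE),
               0.0585 / sqrt(1 + 2.785^2))
})

test_that("windowed stand-in track scores charge against hydropathy", {
  polyE <- strrep("E", 40)
  polyI <- strrep("I", 40)
  expect_true(all(internal_track(polyE) > 0.5))
  expect_true(all(internal_track(polyI) < 0.5))
  # ordered domain inside disordered flanks scores lower than the flanks
  fam <- default_family()
  pid <- names(fam$seqs)[1]
  reg <- fam$regions[fam$regions$id == pid, ]
  tr <- internal_track(fam$seqs[[pid]])
  ap2 <- idrscape:::region_mask(nchar(fam$seqs[[pid]]),
                                reg[reg$label == "AP2", ])
  expect_lt(mean(tr[ap2]), mean(tr[!ap2]))
})

test_that("stand-in track commutes with sequence reversal", {
  set.seed(31)
  for (i in 1:5) {
    s <- paste(sample(AA20, 60, replace = TRUE), collapse = "")
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(as.numeric(internal_track(rev_s)),
                 rev(as.numeric(internal_track(s))))
  }
})

test_that("track ingestion validates positions, residues and range", {
  seqs <- c(p1 = "MKV")
  p <- write_tmp(c("id\tposition\tresidue\tscore",
                   "p1\t1\tM\t0.2", "p1\t2\tK\t0.9", "p1\t3\tV\t0.5"))
  tr <- read_track(p, seqs)
  expect_length(tr$p1, 3L)

  bad <- write_tmp(c("id\tposition\tresidue\tscore",
                     "p1\t1\tM\t0.2", "p1\t2\tA\t0.9", "p1\t3\tV\t0.5"))
  expect_error(read_track(bad, seqs), "mismatch")

  gap <- write_tmp(c("id\tposition\tresidue\tscore",
                     "p1\t1\tM\t0.2", "p1\t3\tV\t0.5"))
  expect_error(read_track(gap, seqs), "consecutive")

  clamp <- write_tmp(c("id\tposition\tresidue\tscore",
                       "p1\t1\tM\t1.2", "p1\t2\tK\t0.9", "p1\t3\tV\t0.5"))
  expect_warning(tr <- read_track(clamp, seqs), "clamped")
  expect_equal(tr$p1[1], 1.0)
})

test_that("CDF curves hit the fully ordered and disordered limits", {
  allhi <- cdf_curve(rep(1.0, 50))
  expect_equal(allhi$cdf_values, rep(0, 9))
  alllo <- cdf_curve(rep(0.0, 50))
  expect_equal(alllo$cdf_values, rep(1, 9))
  # two-point distribution at 0.25/0.75 pins the curve at 0.5 in between
  two <- cdf_curve(rep(c(0.25, 0.75), each = 25))
  mid <- two$bins >= 0.3 & two$bins <= 0.7
  expect_equal(two$cdf_values[mid], rep(0.5, sum(mid)))
  expect_error(cdf_curve(numeric(0)), "empty")
})

test_that("CDF curves are monotone and bounded for random tracks", {
  set.seed(77)
  for (i in 1:20) {
    sc <- runif(sample(5:200, 1))
    cv <- cdf_curve(sc)$cdf_values
    expect_true(all(diff(cv) >= 0))
    expect_true(all(cv >= 0 & cv <= 1))
  }
})

test_that("quadrant assignment matches the phase-space semantics", {
  expect_equal(chcdf_quadrant(0.05, 0.1), "Q1")   # CH disordered, CDF ordered
  expect_equal(chcdf_quadrant(-0.05, 0.1), "Q2")  # ordered by both
  expect_equal(chcdf_quadrant(-0.05, -0.1), "Q3") # CDF disordered, CH compact
  expect_equal(chcdf_quadrant(0.05, -0.1), "Q4")  # disordered by both
  # exhaustive and mutually exclusive over sign patterns; zero goes to the
  # ordered call on each axis
  grid <- expand.grid(ch = c(-1, 0, 1), cdf = c(-1, 0, 1))
  q <- mapply(chcdf_quadrant, grid$ch, grid$cdf)
  expect_true(all(q %in% c("Q1", "Q2", "Q3", "Q4")))
  expect_equal(chcdf_quadrant(0, 0), "Q2")
  expect_equal(chcdf_quadrant(0, -0.1), "Q3")
  expect_equal(chcdf_quadrant(0.1, 0), "Q1")
})

test_that("designed compositional extremes separate on the CH plot", {
  set.seed(101)
  charged <- vapply(1:50, function(i)
    paste(sample(c("E", "D", "K", "S", "P", "Q", "G"), 100, replace = TRUE),
          collapse = ""), character(1))
  hydrophobic <- vapply(1:50, function(i)
    paste(sample(c("I", "L", "V", "F", "A", "M", "W"), 100, replace = TRUE),
          collapse = ""), character(1))
  d_charged <- vapply(charged, function(s) ch_point(s)$ch_distance, numeric(1))
  d_hydro <- vapply(hydrophobic, function(s) ch_point(s)$ch_distance, numeric(1))
  expect_true(all(d_charged > 0))
  expect_true(all(d_hydro < 0))
})

test_that("IDAA% counts residues at or above the threshold", {
  expect_equal(idaa_fraction(c(0.6, 0.6, 0.4, 0.5)), 75.0)
  expect_equal(idaa_fraction(rep(0.9, 10)), 100.0)
  expect_equal(idaa_fraction(rep(0.1, 10)), 0.0)
  expect_error(idaa_fraction(numeric(0)), "empty")
  # monotone non-increasing in the threshold
  set.seed(13)
  sc <- runif(200)
  vals <- vapply(seq(0.1, 0.9, 0.1), function(t) idaa_fraction(sc, t),
                 numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("calibrated CDF boundary lies between the reference curves", {
  set.seed(3)
  ord <- lapply(1:20, function(i) rbeta(100, 2, 8))
  dis <- lapply(1:20, function(i) rbeta(100, 8, 2))
  b <- calibrate_cdf_boundary(ord, dis)
  expect_length(b, 9L)
  # ordered tracks sit above the boundary (positive distance), disordered below
  expect_true(all(vapply(ord, function(t)
    cdf_curve(t, boundary = b)$cdf_distance, numeric(1)) > 0))
  expect_true(all(vapply(dis, function(t)
    cdf_curve(t, boundary = b)$cdf_distance, numeric(1)) < 0))
  # empirical calibration approximates the closed-form default
  expect_equal(b, cdf_default_boundary(), tolerance = 0.05)
})
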