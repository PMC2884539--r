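test_that("angle identities hold exactly", {
  r <- computeAngle(c(0, 3, 2), c(5, 0, 2))
  expect_equal(r$angle_deg, c(0, 90, 45))
  expect_equal(r$c_dist[3], 2 * sqrt(2))
  expect_error(computeAngle(-1, 1), "non-negative")
  nd <- computeAngle(0, 0)
  expect_equal(nd$status, "no_data")
  expect_true(is.na(nd$angle_deg))
})

test_that("the angle is scale invariant and c is Euclidean, exactly", {
  set.seed(31)
  for (i in 1:50) {
    h <- runif(1, 0, 100); m <- runif(1, 0, 100); k <- runif(1, 0.01, 50)
    a1 <- computeAngle(h, m); a2 <- computeAngle(k * h, k * m)
    expect_equal(a1$angle_deg, a2$angle_deg, tolerance = 1e-12)
    expect_equal(a2$c_dist, k * a1$c_dist, tolerance = 1e-12)
    expect_equal(a1$c_dist^2, h^2 + m^2, tolerance = 1e-12)
  }
})

test_that("the angle increases strictly in HpaII signal at fixed MspI", {
  h <- seq(0, 50, by = 0.5)
  ang <- computeAngle(h, rep(7, length(h)))$angle_deg
  expect_true(all(diff(ang) > 0))
})

test_that("scoring flags unassayed sites and validates universes", {
  sites <- mk_sites(c(100L, 200L, 300L))
  hp <- SiteCounts(sites, c(0, 2, 0), "HpaII")
  ms <- SiteCounts(sites, c(4, 2, 0), "MspI")
  ang <- scoreSample(hp, ms)
  expect_s4_class(ang, "AngleRecords")
  expect_equal(scoreStatus(ang), c("scored", "scored", "no_data"))
  expect_equal(angles(ang)[1], 0)
  expect_true(is.na(angles(ang)[3]))
  other <- SiteCounts(mk_sites(c(100L, 200L, 304L)), c(1, 1, 1), "MspI")
  expect_error(scoreSample(hp, other), "universes differ")
})

test_that("an all-zero MspI sample yields only 90-degree or no_data sites", {
  sites <- mk_sites(c(100L, 200L, 300L))
  hp <- SiteCounts(sites, c(3, 0, 1), "HpaII")
  ms <- SiteCounts(sites, c(0, 0, 0), "MspI")
  ang <- scoreSample(hp, ms)
  sc <- scoreStatus(ang) == "scored"
  expect_true(all(angles(ang)[sc] == 90))
  expect_equal(scoreStatus(ang)[2], "no_data")
})

test_that("reference correlation matches the closed-form oracle", {
  set.seed(32)
  a <- runif(40, 0, 90)
  ref <- 1 - a / 90 + rnorm(40, 0, 0.05)
  res <- correlateWithReference(a, ref)
  r_oracle <- sum((a - mean(a)) * (ref - mean(ref))) /
    sqrt(sum((a - mean(a))^2) * sum((ref - mean(ref))^2))
  expect_equal(res$pearson_r, r_oracle, tolerance = 1e-12)
  expect_equal(res$r_squared, r_oracle^2, tolerance = 1e-12)

  perfect <- correlateWithReference(c(0, 45, 90), c(1, 0.5, 0))
  expect_equal(perfect$r_squared, 1)
  expect_error(correlateWithReference(c(1, 2, 3), c(1, 1, 1)), "constant")
  expect_error(correlateWithReference(c(1, 2), c(1, 2)), "at least 3")
})

test_that("angle recovery beats raw counts on simulated data", {
  ms <- countLibrary(lib_small_mspi, sim_small$genome, sim_small$sites)
  hp <- countLibrary(simulateLibrary(sim_small, "HpaII"),
                     sim_small$genome, sim_small$sites)
  ang <- scoreSample(hp, ms)
  tr <- sim_small$truth
  ok <- scoreStatus(ang) == "scored"
  r2_angle <- cor(angles(ang)[ok], tr$m[ok])^2
  r2_raw <- cor(tagCounts(hp), tr$m)^2
  expect_gt(r2_angle, r2_raw)
  expect_gt(cor(angles(ang)[ok], 1 - tr$m[ok], method = "spearman"), 0.8)
})

test_that("track export writes the sentinel and omits untested loci", {
  sites <- mk_sites(c(99L, 199L, 299L))
  ang <- new("AngleRecords", sites = sites,
             angle = c(72.5, 0, NA), cDist = c(10, 5, 0),
             status = c("scored", "scored", "no_data"))
  wig <- tempfile(fileext = ".wig")
  bed <- tempfile(fileext = ".bed")
  exportTracks(ang, wig, bed)
  lines <- readLines(wig)
  expect_match(lines[1], "^track type=wiggle_0")
  expect_true("100 72.5" %in% lines)     # 0-based 99 -> 1-based 100
  expect_true("200 -1" %in% lines)       # zero angle sentinel
  expect_false(any(grepl("^300 ", lines)))
  b <- read.delim(bed, header = FALSE)
  expect_equal(b$V2, 299L)

  none <- new("AngleRecords", sites = mk_sites(integer(0)),
              angle = numeric(0), cDist = numeric(0),
              status = character(0))
  exportTracks(none, wig)
  expect_equal(length(readLines(wig)), 1L)  # header only
})
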