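# crafted alignment rows adjacent to given sites
mk_aln <- function(read_id, start, strand = "+", n_hits = 1L,
                   chrom = "chr1") {
  data.frame(read_id = read_id, tag = strrep("A", 27), chrom = chrom,
             start = start, strand = strand, mismatches = 0L,
             n_hits = n_hits, stringsAsFactors = FALSE)
}

test_that("an alignment adjacent to a site contributes its full weight", {
  sites <- mk_sites(c(100L, 400L))
  # plus strand: nominal site position is start + 24
  sc <- assignToSites(mk_aln("r1", 76L), sites, "MspI")
  expect_equal(tagCounts(sc), c(1, 0))
  # minus strand: nominal site position is start - 1
  sc <- assignToSites(mk_aln("r2", 401L, strand = "-"), sites, "MspI")
  expect_equal(tagCounts(sc), c(0, 1))
  # slack of 2 bp still assigns; 3 bp does not
  sc <- assignToSites(mk_aln("r3", 74L), sites, "MspI")
  expect_equal(tagCounts(sc), c(1, 0))
  sc <- assignToSites(mk_aln("r4", 73L), sites, "MspI")
  expect_equal(tagCounts(sc), c(0, 0))
  expect_equal(nrow(sc@unassigned), 1L)
})

test_that("multi-mapping reads are spread as 1/n partial counts", {
  sites <- mk_sites(c(100L, 200L, 300L, 400L))
  aln <- do.call(rbind, lapply(c(76L, 176L, 276L, 376L), function(s)
    mk_aln("r1", s, n_hits = 4L)))
  sc <- assignToSites(aln, sites, "MspI")
  expect_equal(tagCounts(sc), rep(0.25, 4))
  expect_equal(sc@nRetained, 1)
})

test_that("nearest site wins with exact matches preferred", {
  sites <- mk_sites(c(100L, 102L))
  # implied position 100 matches site 1 exactly
  sc <- assignToSites(mk_aln("r1", 76L), sites, "MspI")
  expect_equal(tagCounts(sc), c(1, 0))
  # implied position 101 ties at distance 1; lower coordinate wins
  sc <- assignToSites(mk_aln("r2", 77L), sites, "MspI")
  expect_equal(tagCounts(sc), c(1, 0))
  # implied position 102 matches site 2 exactly
  sc <- assignToSites(mk_aln("r3", 78L), sites, "MspI")
  expect_equal(tagCounts(sc), c(0, 1))
})

test_that("weight is conserved through counting, exactly", {
  sc <- countLibrary(lib_small_mspi, sim_small$genome, sim_small$sites)
  total <- sum(tagCounts(sc)) + sum(sc@unassigned$weight)
  expect_equal(total, sc@nRetained, tolerance = 1e-9)
  # retained + dropped = anchored input reads
  anchored <- sum(!is.na(findAnchor(lib_small_mspi$reads)))
  expect_equal(sc@nRetained + sum(sc@dropped$reads), anchored)
})

test_that("fixed counts normalize a sample to unit total", {
  sites <- mk_sites(c(100L, 200L, 300L))
  sc <- SiteCounts(sites, c(2, 3, 5), "MspI")
  expect_equal(fixedCounts(sc), c(0.2, 0.3, 0.5))
  expect_equal(sum(fixedCounts(sc)), 1, tolerance = 1e-12)
  one <- SiteCounts(sites, c(0, 7, 0), "MspI")
  expect_equal(fixedCounts(one), c(0, 1, 0))
  zero <- SiteCounts(sites, c(0, 0, 0), "MspI")
  expect_error(fixedCounts(zero), "all-zero")
})

test_that("replicate correlation behaves on degenerate inputs", {
  sites <- mk_sites(c(100L, 200L))
  a <- SiteCounts(sites, c(1, 0), "MspI")
  b <- SiteCounts(sites, c(0, 1), "MspI")
  expect_equal(replicateCorrelation(a, a), 1)
  expect_equal(replicateCorrelation(a, b), -1)
  flat <- SiteCounts(sites, c(2, 2), "MspI")
  expect_error(replicateCorrelation(flat, a), "zero variance")
  other <- SiteCounts(mk_sites(c(100L, 204L)), c(1, 0), "MspI")
  expect_error(replicateCorrelation(a, other), "universes differ")
})

test_that("merging lanes sums counts and commutes with fixing", {
  sites <- mk_sites(c(100L, 200L, 300L))
  x <- SiteCounts(sites, c(1, 2, 3), "MspI")
  m3 <- mergeLanes(x, x, x)
  expect_equal(tagCounts(m3), c(3, 6, 9))
  expect_identical(tagCounts(mergeLanes(x)), tagCounts(x))
  y <- SiteCounts(sites, c(4, 0, 1), "MspI")
  expect_equal(fixedCounts(mergeLanes(x, y)),
               (tagCounts(x) + tagCounts(y)) / sum(tagCounts(x) + tagCounts(y)))
  z <- SiteCounts(mk_sites(c(100L, 200L, 304L)), c(1, 1, 1), "MspI")
  expect_error(mergeLanes(x, z), "universes differ")
  h <- SiteCounts(sites, c(1, 1, 1), "HpaII")
  expect_error(mergeLanes(x, h), "different enzymes")
})

test_that("coverage summary reports zero-class and mean depth", {
  sites <- mk_sites(c(100L, 200L))
  expect_equal(coverageSummary(SiteCounts(sites, c(0, 0), "MspI")),
               list(fraction_covered = 0, mean_reads = 0))
  expect_equal(coverageSummary(SiteCounts(sites, c(1, 0), "MspI")),
               list(fraction_covered = 0.5, mean_reads = 0.5))
})

test_that("count tables round-trip through TSV", {
  sc <- countLibrary(lib_small_mspi, sim_small$genome, sim_small$sites)
  path <- tempfile(fileext = ".tsv")
  writeCounts(sc, path)
  back <- readCounts(path, "MspI")
  expect_equal(tagCounts(back), tagCounts(sc), tolerance = 1e-9)
  expect_identical(back@sites$site_id, sc@sites$site_id)
})

test_that("simulated counts recover the planted truth structure", {
  sc <- countLibrary(lib_small_mspi, sim_small$genome, sim_small$sites)
  tr <- sim_small$truth
  # MspI blind to methylation
  expect_lt(abs(cor(tagCounts(sc), tr$m)), 0.25)
  # counts track efficiency
  expect_gt(cor(tagCounts(sc), tr$efficiency), 0.5)
  hp <- countLibrary(simulateLibrary(sim_small, "HpaII"),
                     sim_small$genome, sim_small$sites)
  expect_lt(cor(tagCounts(hp) / tr$efficiency, tr$m), -0.6)
})
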