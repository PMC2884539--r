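test_that("simulation is a pure function of its seed", {
  cfg <- simConfig(n_sites = 60L, chrom_length = 12000L, seed = 7L,
                   n_repeat_copies = 2L, n_lost = 3L, n_gained = 3L)
  a <- simulateGenome(cfg)
  b <- simulateGenome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.character(a$sampleGenome),
                   as.character(b$sampleGenome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$gained, b$gained)
  la <- simulateLibrary(a, "HpaII")
  lb <- simulateLibrary(b, "HpaII")
  expect_identical(la$reads, lb$reads)
  expect_identical(la$meta, lb$meta)
})

test_that("configuration invariants are enforced", {
  expect_error(simConfig(seed = 1, junk_fraction = 1.2), "rates")
  expect_error(simConfig(seed = 1, cut_length_probs =
                           c(`25` = 0.5, `26` = 0.5, `27` = 0.1)), "sum to 1")
  expect_error(simConfig(n_sites = 1000, chrom_length = 5000, seed = 1) |>
                 simulateGenome(), "too short")
  expect_error(simConfig(), "seed")
})

test_that("no islands are annotated when the island fraction is zero", {
  sim <- simulateGenome(simConfig(n_sites = 50L, chrom_length = 10000L,
                                  seed = 3L, gc_island_fraction = 0))
  expect_equal(length(sim$islands), 0L)
  expect_false(any(sim$truth$category == "island"))
})

test_that("methylation fractions follow the configured mixture", {
  sim <- simulateGenome(simConfig(n_sites = 1000L, chrom_length = 150000L,
                                  seed = 5L, gc_island_fraction = 0,
                                  n_repeat_copies = 0L))
  m <- sim$truth$m
  # binomial sampling error: 4 sd at n = 1000 is ~0.062
  expect_equal(mean(m == 0), 0.4, tolerance = 0.17)
  expect_equal(mean(m == 1), 0.4, tolerance = 0.17)
  mid <- m > 0 & m < 1
  expect_equal(mean(mid), 0.2, tolerance = 0.3)
  expect_gt(diff(range(m[mid])), 0.5)  # middle component is spread out
})

test_that("fully methylated sites yield no HpaII reads", {
  lib <- simulateLibrary(sim_small, "HpaII")
  m1 <- sim_small$truth$site_id[sim_small$truth$m == 1]
  expect_gt(length(m1), 0L)
  expect_false(any(lib$meta$site_id %in% m1))
  # but MspI reads them regardless of methylation
  expect_true(any(lib_small_mspi$meta$site_id %in% m1))
})

test_that("realized read counts follow the expected Poisson intensities", {
  exp_tot <- sum(lib_small_mspi$expected$expected_reads)
  obs_tot <- sum(lib_small_mspi$meta$origin != "junk")
  expect_lt(abs(obs_tot - exp_tot), 5 * sqrt(exp_tot))
  # per-site standardized residuals are not wildly off
  cnt <- meta_site_counts(lib_small_mspi, sim_small$truth$site_id)
  exp_site <- lib_small_mspi$expected
  exp_site <- exp_site[match(sim_small$truth$site_id, exp_site$site_id), ]
  z <- (cnt - exp_site$expected_reads) / sqrt(pmax(exp_site$expected_reads, 1))
  expect_lt(mean(abs(z) > 4), 0.01)
})

test_that("anchor positions concentrate at the 25/26 cut lengths", {
  ap <- findAnchor(lib_small_mspi$reads)
  tab <- table(ap)
  expect_true(names(tab)[which.max(tab)] %in% c("25", "26"))
  expect_gt(sum(tab[names(tab) %in% c("25", "26")]) / sum(tab), 0.8)
})

test_that("MspI intensity ignores methylation while HpaII decreases in it", {
  sim <- simulateGenome(simConfig(n_sites = 1000L, chrom_length = 150000L,
                                  seed = 9L, gc_island_fraction = 0,
                                  n_repeat_copies = 0L,
                                  lenfactor_floor = 1))
  mspi <- simulateLibrary(sim, "MspI")
  hpa <- simulateLibrary(sim, "HpaII")
  cm <- meta_site_counts(mspi, sim$truth$site_id)
  ch <- meta_site_counts(hpa, sim$truth$site_id)
  expect_lt(abs(cor(cm, sim$truth$m)), 0.1)
  # remove efficiency variation to isolate the methylation effect
  expect_lt(cor(ch / sim$truth$efficiency, sim$truth$m), -0.8)
  # expected intensities are exactly monotone in m at fixed efficiency
  eh <- hpa$expected$expected_reads[match(sim$truth$site_id,
                                          hpa$expected$site_id)]
  base <- eh / (1 - sim$truth$m)
  keep <- sim$truth$m < 1
  expect_equal(eh[keep], base[keep] * (1 - sim$truth$m[keep]))
})

test_that("junk reads lack the anchor and match the configured fraction", {
  meta <- lib_small_mspi$meta
  junk <- meta$origin == "junk"
  expect_true(all(is.na(findAnchor(lib_small_mspi$reads[junk]))))
  expect_equal(mean(junk), 0.3, tolerance = 0.1)
})

test_that("FASTQ round-trip preserves reads", {
  path <- tempfile(fileext = ".fq.gz")
  writeFastq(lib_small_mspi, path)
  back <- readFastq(path)
  expect_identical(unname(back), unname(lib_small_mspi$reads))
  expect_identical(names(back), names(lib_small_mspi$reads))
})

test_that("planted variants alter only the sampled genome", {
  sim <- simulateGenome(simConfig(n_sites = 80L, chrom_length = 15000L,
                                  seed = 13L, n_lost = 5L, n_gained = 5L))
  ref <- as.character(sim$genome[[1]])
  smp <- as.character(sim$sampleGenome[[1]])
  for (i in which(sim$truth$lost)) {
    p <- sim$truth$pos[i]
    expect_identical(substr(ref, p + 1, p + 4), "CCGG")
    expect_identical(substr(smp, p + 1, p + 4),
                     sim$truth$variant_tetramer[i])
  }
  for (k in seq_len(nrow(sim$gained))) {
    p <- sim$gained$pos[k]
    expect_identical(substr(ref, p + 1, p + 4), sim$gained$ref_tetramer[k])
    expect_identical(substr(smp, p + 1, p + 4), "CCGG")
  }
  # lost sites yield no reads; gained loci do
  lib <- simulateLibrary(sim, "MspI")
  expect_false(any(lib$meta$site_id %in%
                     sim$truth$site_id[sim$truth$lost]))
  expect_true(any(lib$meta$origin == "gained"))
})
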