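test_that("substitutions are classified strand-folded", {
  expect_equal(classifySubstitution("CTGG"), "C:G>T:A")
  expect_equal(classifySubstitution("CCAG"), "C:G>T:A")
  expect_equal(classifySubstitution("ACGG"), "C:G>A:T")
  expect_equal(classifySubstitution("CCGT"), "C:G>A:T")
  expect_equal(classifySubstitution("CCGC"), "C:G>G:C")
  expect_error(classifySubstitution("CTAG"), "2 positions")
  expect_error(classifySubstitution("CCGG"), "0 positions")
})

test_that("planted variants are mostly deamination-type", {
  sim <- simulateGenome(simConfig(n_sites = 400L, chrom_length = 60000L,
                                  seed = 51L, n_lost = 60L, n_gained = 60L,
                                  n_repeat_copies = 0L))
  tets <- c(sim$truth$variant_tetramer[sim$truth$lost],
            sim$gained$ref_tetramer)
  cls <- vapply(tets, classifySubstitution, character(1))
  # 120 draws at 80%: 4 sd is ~0.15
  expect_equal(mean(cls == "C:G>T:A"), 0.8, tolerance = 0.2)
})

test_that("zero MspI evidence defines lost candidates strictly", {
  sites <- mk_sites(c(100L, 200L, 300L))
  sc <- SiteCounts(sites, c(0, 0.25, 5), "MspI")
  res <- detectLostSites(sc)
  expect_equal(res$candidates$site_id, 1L)
  expect_true(all(is.na(res$candidates$variant_match)))
  expect_equal(nrow(res$variant_filtered), 0L)

  vars <- GRanges("chr1", IRanges::IRanges(102, 102), id = "rs1",
                  ref = "C", alt = "T")
  res <- detectLostSites(sc, vars)
  expect_equal(res$candidates$variant_match, "rs1")
  expect_equal(res$candidates$substitution_class, "C:G>T:A")
  expect_equal(nrow(res$variant_filtered), 1L)
})

test_that("gained-site calling applies a strict minimum-weight cutoff", {
  set.seed(52)
  g <- paste0(rand_seq(500), "CTGG", rand_seq(500))
  sites <- mk_sites(integer(0))
  mk_un <- function(w) data.frame(
    read_id = sprintf("r%d", seq_along(w)), tag = strrep("A", 27),
    chrom = "seq1", start = 476L, strand = "+", mismatches = 1L,
    n_hits = 1L, weight = w, implied_pos = 500L,
    stringsAsFactors = FALSE)
  below <- detectGainedSites(mk_un(c(2, 1.5)), c(seq1 = g), sites)
  expect_equal(nrow(below$candidates), 0L)
  expect_equal(below$rejected$reason, "below_min_reads")
  at <- detectGainedSites(mk_un(c(2, 2)), c(seq1 = g), sites)
  expect_equal(at$candidates$pos, 500L)
  expect_equal(at$candidates$ref_tetramer, "CTGG")
  expect_equal(at$candidates$substitution_class, "C:G>T:A")
  expect_error(detectGainedSites(mk_un(4), c(seq1 = g), sites,
                                 min_reads = 0), "min_reads")
})

test_that("clusters without a one-substitution context are rejected", {
  set.seed(54)
  g <- paste0(rand_seq(500), "CTAG", rand_seq(500))  # two differences
  # scrub chance CCGG neighbors around the probe window
  sites <- mk_sites(integer(0))
  un <- data.frame(read_id = "r1", tag = strrep("A", 27), chrom = "seq1",
                   start = 476L, strand = "+", mismatches = 2L,
                   n_hits = 1L, weight = 5, implied_pos = 500L,
                   stringsAsFactors = FALSE)
  res <- detectGainedSites(un, c(seq1 = g), sites)
  if (nrow(res$candidates) == 0L)
    expect_equal(res$rejected$reason, "no_single_substitution_tetramer")
  expect_false(500L %in% res$candidates$pos)
})

test_that("planted lost and gained sites are recovered from reads", {
  cfg <- simConfig(n_sites = 300L, chrom_length = 45000L, seed = 53L,
                   n_lost = 15L, n_gained = 15L, efficiency_sigma = 0,
                   lenfactor_floor = 1, junk_fraction = 0)
  sim <- simulateGenome(cfg)
  lanes <- lapply(c(1L, 2L), function(s)
    countLibrary(simulateLibrary(sim, "MspI", seed = cfg$seed + s),
                 sim$genome, sim$sites))
  merged <- mergeLanes(lanes)

  lost <- detectLostSites(merged)$candidates
  truth_lost <- sim$truth$site_id[sim$truth$lost]
  sens <- mean(truth_lost %in% lost$site_id)
  prec <- mean(lost$site_id %in% truth_lost)
  expect_gte(sens, 0.9)
  expect_gte(prec, 0.9)

  gained <- detectGainedSites(merged, sim$genome, sim$sites)$candidates
  hit <- vapply(sim$gained$pos, function(p)
    any(abs(gained$pos - p) <= 2), logical(1))
  expect_gte(mean(hit), 0.9)
  prec_g <- mean(vapply(gained$pos, function(p)
    any(abs(sim$gained$pos - p) <= 2), logical(1)))
  expect_gte(prec_g, 0.9)

  # structural invariants: annotated never gained, unannotated never lost
  expect_false(any(gained$pos %in% sim$truth$pos))
  expect_true(all(lost$site_id %in% sim$truth$site_id))
})
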