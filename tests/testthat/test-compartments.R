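test_that("sites receive exactly one compartment label", {
  sites <- mk_sites(c(9000L, 15000L, 60000L))
  genes <- GRanges("chr1", IRanges::IRanges(10001, 30000), strand = "+")
  ann <- annotateSites(sites, genes)
  expect_equal(nrow(ann), 3L)
  expect_false(any(is.na(ann$compartment)))

  # 1 kb upstream of a plus-strand TSS: promoter, negative distance
  expect_equal(ann$compartment[1], "promoter")
  expect_equal(ann$tss_distance[1], -1000L)
  # 5 kb into the gene body
  expect_equal(ann$compartment[2], "gene_body")
  expect_equal(ann$tss_distance[2], 5000L)
  # 50 kb away
  expect_equal(ann$compartment[3], "intergenic")

  # minus-strand orientation flips the sign
  genes_m <- GRanges("chr1", IRanges::IRanges(1, 10001), strand = "-")
  ann_m <- annotateSites(mk_sites(9000L), genes_m)
  expect_equal(ann_m$tss_distance, 1000L)  # downstream of a minus TSS

  expect_error(annotateSites(sites, GRanges("chr1", IRanges::IRanges(1, 10))),
               "stranded")
})

test_that("repeat overlap is passed through as repeat_class", {
  sites <- mk_sites(c(100L, 500L))
  genes <- GRanges("chr1", IRanges::IRanges(5000, 6000), strand = "+")
  rpt <- GRanges("chr1", IRanges::IRanges(90, 140), family = "AluY")
  ann <- annotateSites(sites, genes, rpt)
  expect_equal(ann$repeat_class, c("AluY", NA))
})

test_that("compartment densities reflect planted methylation structure", {
  sim <- simulateGenome(simConfig(n_sites = 300L, chrom_length = 50000L,
                                  seed = 61L, gc_island_fraction = 0.15,
                                  n_repeat_copies = 8L))
  ms <- countLibrary(simulateLibrary(sim, "MspI"), sim$genome, sim$sites)
  hp <- countLibrary(simulateLibrary(sim, "HpaII"), sim$genome, sim$sites)
  ang <- scoreSample(hp, ms)

  # genes start at island sites: islands are unmethylated promoters
  isl <- sim$truth$pos[sim$truth$category == "island"]
  genes <- GRanges(sim$config$chrom_name,
                   IRanges::IRanges(isl + 1L, isl + 3000L), strand = "+")
  ann <- annotateSites(sim$sites, genes, sim$repeats)

  dens <- compartmentDensity(ang, ann)
  med <- setNames(dens$summary$median_angle, dens$summary$group)
  expect_gt(med[["promoter"]], med[["intergenic"]])

  byrep <- compartmentDensity(ang, ann, by = "repeat")
  medr <- setNames(byrep$summary$median_angle, byrep$summary$group)
  expect_lt(medr[["repeat"]], medr[["unique"]])

  # identical angles give identical distributions everywhere
  flat <- new("AngleRecords", sites = sim$sites,
              angle = rep(45, length(sim$sites)),
              cDist = rep(1, length(sim$sites)),
              status = rep("scored", length(sim$sites)))
  dflat <- compartmentDensity(flat, ann)
  expect_true(all(dflat$summary$median_angle == 45))
})

test_that("TSS profiles tabulate angle classes by distance", {
  n <- 60L
  sites <- mk_sites(seq(0L, by = 500L, length.out = n))
  ann <- data.frame(site_id = seq_len(n), compartment = "intergenic",
                    repeat_class = rep(c("SIM", NA), n / 2),
                    tss_distance = seq(-7500, 7250, by = 250)[seq_len(n)])
  allhigh <- new("AngleRecords", sites = sites, angle = rep(75, n),
                 cDist = rep(1, n), status = rep("scored", n))
  prof <- tssProfile(allhigh, ann, bin_bp = 2500L, max_dist = 10000L)
  pops <- rowSums(prof$counts) > 0
  expect_true(all(prof$percent[pops, "61-90"] == 100))
  expect_equal(rowSums(prof$percent[pops, , drop = FALSE]),
               rep(100, sum(pops)), ignore_attr = TRUE)
  expect_equal(sum(prof$counts), prof$n_in_range)

  # promoter-proximal repeats unmethylated: high-angle share declines
  # with distance among repeat sites
  ang <- ifelse(abs(ann$tss_distance) < 3000, 80, 10)
  grad <- new("AngleRecords", sites = sites, angle = ang,
              cDist = rep(1, n), status = rep("scored", n))
  prof_r <- tssProfile(grad, ann, bin_bp = 5000L, max_dist = 10000L,
                       repeat_only = TRUE)
  share <- prof_r$percent[, "61-90"]
  mid <- abs(prof_r$bin_mid) < 3000
  expect_true(min(share[mid], na.rm = TRUE) >
              max(share[!mid], na.rm = TRUE))

  expect_error(tssProfile(grad, ann, bin_bp = 0), "positive")
})
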