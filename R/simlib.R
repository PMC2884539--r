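#' Simulation configuration
#'
#' Parameters of the in-silico HELP-tagging experiment. Defaults are
#' the package's reference study conditions: 2,000 CCGG sites on one
#' chromosome, mean sequencing depth 20 reads per site per enzyme,
#' lognormal per-site capture efficiency with sigma 1, EcoP15I cut
#' lengths concentrated on 25-26 bp, ~30% junk reads without the
#' adapter anchor, and a bimodal methylation landscape (spikes near 0
#' and 1 plus a uniform middle component).
#'
#' @param n_sites number of annotated CCGG sites planted.
#' @param chrom_length chromosome length in bp.
#' @param seed integer RNG seed; required, all output is a pure
#'   function of the configuration.
#' @param gc_background background G+C fraction.
#' @param gc_island_fraction fraction of sites placed in GC-rich
#'   islands (these sites are simulated hypomethylated, like CpG
#'   islands at active promoters).
#' @param island_gc G+C fraction inside islands.
#' @param island_halfwidth half-width of an island region, bp.
#' @param depth mean reads per site per enzyme (split evenly over the
#'   two flanks of the cut).
#' @param efficiency_sigma sdlog of the lognormal per-site capture
#'   efficiency.
#' @param cut_length_probs named probabilities over EcoP15I cut
#'   lengths 25/26/27 bp.
#' @param junk_fraction fraction of the library that is random
#'   sequence lacking the adapter anchor.
#' @param error_rate per-base substitution error rate.
#' @param n_repeat_copies copies of a planted repetitive element, each
#'   containing one CCGG (these sites multi-map and are simulated
#'   methylated, like transposable elements).
#' @param repeat_length length of the repetitive element, bp.
#' @param n_lost annotated sites destroyed by a planted variant in the
#'   sampled individual (no reads generated).
#' @param n_gained loci where a planted variant creates a CCGG absent
#'   from the reference (reads generated, site unannotated).
#' @param deam_fraction fraction of planted variants that are
#'   deamination-type C:G>T:A substitutions at the methylated CG.
#' @param meth_weights mixture weights (low spike, high spike,
#'   uniform middle) for background-site methylation fractions.
#' @param lenfactor_floor relative sequencing efficiency of fragments
#'   >= 1000 bp; 1 disables the fragment-length bias. Fragments
#'   <= 300 bp have efficiency 1, with a linear decline to the floor
#'   at 1000 bp.
#' @param high_gc_penalty capture-efficiency multiplier applied to
#'   sites whose 50-bp GC content exceeds `high_gc_threshold`; 1
#'   disables the GC bias.
#' @param high_gc_threshold GC percent above which the penalty applies.
#' @param chrom_name name of the simulated chromosome.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(n_sites = 2000L,
                      chrom_length = as.integer(n_sites) * 150L,
                      seed,
                      gc_background = 0.40,
                      gc_island_fraction = 0.10,
                      island_gc = 0.80,
                      island_halfwidth = 200L,
                      depth = 20,
                      efficiency_sigma = 1,
                      cut_length_probs = c(`25` = 0.45, `26` = 0.45, `27` = 0.10),
                      junk_fraction = 0.30,
                      error_rate = 0.005,
                      n_repeat_copies = 6L,
                      repeat_length = 150L,
                      n_lost = 0L,
                      n_gained = 0L,
                      deam_fraction = 0.8,
                      meth_weights = c(low = 0.4, high = 0.4, mid = 0.2),
                      lenfactor_floor = 0.25,
                      high_gc_penalty = 1,
                      high_gc_threshold = 80,
                      chrom_name = "simchr") {
  if (missing(seed)) stop("simConfig requires an explicit seed", call. = FALSE)
  cfg <- list(n_sites = as.integer(n_sites),
              chrom_length = as.integer(chrom_length), seed = as.integer(seed),
              gc_background = gc_background,
              gc_island_fraction = gc_island_fraction, island_gc = island_gc,
              island_halfwidth = as.integer(island_halfwidth),
              depth = depth, efficiency_sigma = efficiency_sigma,
              cut_length_probs = cut_length_probs,
              junk_fraction = junk_fraction, error_rate = error_rate,
              n_repeat_copies = as.integer(n_repeat_copies),
              repeat_length = as.integer(repeat_length),
              n_lost = as.integer(n_lost), n_gained = as.integer(n_gained),
              deam_fraction = deam_fraction, meth_weights = meth_weights,
              lenfactor_floor = lenfactor_floor,
              high_gc_penalty = high_gc_penalty,
              high_gc_threshold = high_gc_threshold, chrom_name = chrom_name)
  rates <- c(gc_background, gc_island_fraction, island_gc, junk_fraction,
             error_rate, deam_fraction)
  if (any(rates < 0) || any(rates > 1))
    stop("all rates and fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cut_length_probs) - 1) > 1e-9)
    stop("cut_length_probs must sum to 1", call. = FALSE)
  if (!identical(names(cut_length_probs), c("25", "26", "27")))
    stop("cut_length_probs must be named '25','26','27'", call. = FALSE)
  if (abs(sum(meth_weights) - 1) > 1e-9)
    stop("meth_weights must sum to 1", call. = FALSE)
  if (lenfactor_floor <= 0 || lenfactor_floor > 1)
    stop("lenfactor_floor must lie in (0, 1]", call. = FALSE)
  class(cfg) <- "SimConfig"
  cfg
}

#' Fragment-length sequencing efficiency
#'
#' Short restriction fragments are sequenced more readily than long
#' ones: efficiency is 1 up to 300 bp, declines linearly to `floor`
#' at 1000 bp, and stays at the floor beyond.
#'
#' @param len fragment length(s), bp.
#' @param floor efficiency for fragments >= 1000 bp.
#' @return numeric vector of multipliers in [floor, 1].
#' @export
lenFactor <- function(len, floor = 0.25) {
  f <- 1 - (1 - floor) * (len - 300) / 700
  pmin(1, pmax(floor, f))
}

# sample random DNA with a given GC fraction
.rand_dna <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Draw a single-substitution neighbor of CCGG. Deamination-type events
# hit the methylatable CG: internal C -> T (CTGG) or its minus-strand
# counterpart G -> A (CCAG).
.draw_variant_tetramer <- function(deam_fraction) {
  if (stats::runif(1) < deam_fraction) {
    return(sample(c("CTGG", "CCAG"), 1L))
  }
  repeat {
    i <- sample.int(4L, 1L)
    ref <- c("C", "C", "G", "G")
    b <- sample(setdiff(DNA_BASES, ref[i]), 1L)
    tet <- ref; tet[i] <- b
    tet <- paste(tet, collapse = "")
    if (!tet %in% c("CTGG", "CCAG")) return(tet)
  }
}

# Mutate the genome (character vector of single bases) until it is free
# of disallowed CCGG / anchor-motif occurrences. Positions listed in
# `allowed_ccgg` (0-based first C) keep their CCGG; `protected` is a
# logical vector of positions that must not be edited.
.scrub_motifs <- function(bases, allowed_ccgg, protected) {
  seqstr <- paste(bases, collapse = "")
  for (iter in 1:50) {
    dirty <- FALSE
    for (pat in c("CCGG", ANCHOR_MOTIF, ANCHOR_MOTIF_RC)) {
      m <- gregexpr(pat, seqstr, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      w <- nchar(pat)
      for (s in as.integer(m)) {
        if (pat == "CCGG" && (s - 1L) %in% allowed_ccgg) next
        span <- s:(s + w - 1L)
        free <- span[!protected[span]]
        if (!length(free))
          stop("cannot scrub motif inside fully protected region", call. = FALSE)
        p <- free[(length(free) + 1L) %/% 2L]
        bases[p] <- if (bases[p] == "A") "T" else "A"
        dirty <- TRUE
      }
    }
    if (!dirty) return(bases)
    seqstr <- paste(bases, collapse = "")
  }
  stop("motif scrubbing did not converge", call. = FALSE)
}

#' Simulate a reference genome with planted CCGG sites and truth
#'
#' Builds a single-chromosome genome containing exactly the planted
#' CCGG sites (spurious CCGG occurrences and adapter-anchor motifs are
#' scrubbed from the background so ground truth is exact), GC-rich
#' island regions around a subset of sites, identical copies of a
#' repetitive element each carrying one CCGG, and optional planted
#' variants that destroy annotated sites (lost) or create unannotated
#' ones (gained) in the sampled individual.
#'
#' Per-site truth: methylation fraction m (islands ~ 0, repeats ~ 1,
#' background from the configured bimodal mixture), lognormal capture
#' efficiency, and a GC-penalty multiplier when the GC bias is enabled.
#'
#' @param config a [simConfig()] object.
#' @return a list of class `HelpTagSim` with elements `genome`
#'   (reference DNAStringSet), `sampleGenome` (with planted variants
#'   applied), `sites` (GRanges of annotated CCGG sites), `truth`
#'   (data.frame: site_id, pos, m, efficiency, gc_multiplier, category,
#'   lost, variant_tetramer), `gained` (data.frame of planted gained
#'   loci), `islands`, `repeats` (GRanges), and `config`.
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withr::with_seed(config$seed, .simulate_genome_impl(config))
}

.simulate_genome_impl <- function(cfg) {
  L <- cfg$chrom_length
  n_ann <- cfg$n_sites
  n_total <- n_ann + cfg$n_gained
  min_gap <- 40L
  margin_lo <- 60L; margin_hi <- 80L
  avail <- L - margin_lo - margin_hi - (n_total - 1L) * min_gap
  if (avail < n_total)
    stop(sprintf("chrom_length %d too short for %d sites", L, n_total),
         call. = FALSE)
  offs <- sort(sample.int(avail, n_total))
  pos_all <- margin_lo + offs + (seq_len(n_total) - 1L) * min_gap  # 0-based
  gained_idx <- if (cfg$n_gained > 0)
    sort(sample.int(n_total, cfg$n_gained)) else integer(0)
  ann_pos <- pos_all[setdiff(seq_len(n_total), gained_idx)]
  gained_pos <- pos_all[gained_idx]

  # choose repeat-copy sites among annotated sites with clearance
  half_rep <- cfg$repeat_length %/% 2L
  rep_sites <- integer(0)
  if (cfg$n_repeat_copies > 0) {
    gaps_lo <- c(ann_pos[1] - 0L, diff(ann_pos))
    gaps_hi <- c(diff(ann_pos), L - ann_pos[n_ann])
    # keep stamped regions clear of neighboring planted loci
    eligible <- which(gaps_lo > half_rep + 20L & gaps_hi > half_rep + 20L &
                      ann_pos > half_rep + 10L &
                      ann_pos + half_rep + 10L < L)
    if (length(gained_pos)) {
      near_gained <- vapply(ann_pos, function(p)
        any(abs(gained_pos - p) <= half_rep + 20L), logical(1))
      eligible <- setdiff(eligible, which(near_gained))
    }
    if (length(eligible) < cfg$n_repeat_copies)
      stop("not enough clearance to place repeat copies", call. = FALSE)
    rep_sites <- sort(sample(eligible, cfg$n_repeat_copies))
  }
  n_island <- round(cfg$gc_island_fraction * n_ann)
  island_pool <- setdiff(seq_len(n_ann), rep_sites)
  island_sites <- sort(sample(island_pool, min(n_island, length(island_pool))))
  lost_pool <- setdiff(seq_len(n_ann), rep_sites)
  if (cfg$n_lost > length(lost_pool))
    stop("n_lost exceeds available non-repeat sites", call. = FALSE)
  lost_sites <- sort(sample(lost_pool, cfg$n_lost))

  bases <- .rand_dna(L, cfg$gc_background)

  # islands: GC-rich region around selected sites
  island_gr <- GRanges()
  if (length(island_sites)) {
    ilo <- pmax(ann_pos[island_sites] - cfg$island_halfwidth, 0L)
    ihi <- pmin(ann_pos[island_sites] + cfg$island_halfwidth + 4L, L)
    for (k in seq_along(ilo)) {
      idx <- (ilo[k] + 1L):ihi[k]
      bases[idx] <- .rand_dna(length(idx), cfg$island_gc)
    }
    island_gr <- GenomicRanges::reduce(
      GRanges(cfg$chrom_name, IRanges::IRanges(ilo + 1L, ihi)))
  }

  # one repetitive element, internally scrubbed, CCGG at its center
  repeat_gr <- GRanges()
  protected <- rep(FALSE, L)
  if (length(rep_sites)) {
    elem <- .rand_dna(cfg$repeat_length, 0.5)
    elem <- .scrub_motifs(elem, allowed_ccgg = integer(0),
                          protected = rep(FALSE, cfg$repeat_length))
    elem[(half_rep + 1L):(half_rep + 4L)] <- c("C", "C", "G", "G")
    # planting CCGG may abut new motif copies; rescrub outside the tetramer
    prot <- rep(FALSE, cfg$repeat_length)
    prot[(half_rep + 1L):(half_rep + 4L)] <- TRUE
    elem <- .scrub_motifs(elem, allowed_ccgg = half_rep, protected = prot)
    starts0 <- ann_pos[rep_sites] - half_rep          # 0-based stamp start
    for (s0 in starts0) {
      idx <- (s0 + 1L):(s0 + cfg$repeat_length)
      bases[idx] <- elem
      protected[idx] <- TRUE
    }
    repeat_gr <- GRanges(cfg$chrom_name,
                         IRanges::IRanges(starts0 + 1L,
                                          starts0 + cfg$repeat_length),
                         family = "SIMREP")
  }

  # plant annotated CCGG (repeat sites already carry theirs)
  for (i in setdiff(seq_len(n_ann), rep_sites)) {
    idx <- (ann_pos[i] + 1L):(ann_pos[i] + 4L)
    bases[idx] <- c("C", "C", "G", "G")
  }
  # gained loci: reference carries a 1-substitution neighbor of CCGG
  gained_ref <- character(0)
  if (length(gained_pos)) {
    gained_ref <- vapply(gained_pos, function(p)
      .draw_variant_tetramer(cfg$deam_fraction), character(1))
    for (k in seq_along(gained_pos)) {
      idx <- (gained_pos[k] + 1L):(gained_pos[k] + 4L)
      bases[idx] <- strsplit(gained_ref[k], "")[[1]]
    }
  }
  for (p in c(ann_pos, gained_pos)) protected[(p + 1L):(p + 4L)] <- TRUE

  bases <- .scrub_motifs(bases, allowed_ccgg = ann_pos, protected = protected)
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- cfg$chrom_name

  sites <- findCCGGSites(genome)
  if (!identical(start(sites) - 1L, as.integer(ann_pos)))
    stop("internal error: scrubbed genome does not match planted sites",
         call. = FALSE)

  gc <- gcWindows(genome, sites)
  gc_mult <- ifelse(!is.na(gc$gc_percent) &
                      gc$gc_percent > cfg$high_gc_threshold,
                    cfg$high_gc_penalty, 1)

  category <- rep("background", n_ann)
  category[island_sites] <- "island"
  category[rep_sites] <- "repeat"
  # bimodal landscape: point masses at 0 (fully unmethylated) and 1
  # (fully methylated) plus a uniform middle component; islands are
  # unmethylated, repeat copies methylated
  m <- numeric(n_ann)
  bg <- which(category == "background")
  comp <- sample(c("low", "high", "mid"), length(bg), replace = TRUE,
                 prob = cfg$meth_weights)
  m[bg] <- ifelse(comp == "low", 0,
           ifelse(comp == "high", 1, stats::runif(length(bg))))
  m[category == "island"] <- 0
  m[category == "repeat"] <- 1
  efficiency <- stats::rlnorm(n_ann, 0, cfg$efficiency_sigma)

  lost <- seq_len(n_ann) %in% lost_sites
  variant_tetramer <- rep(NA_character_, n_ann)
  if (any(lost))
    variant_tetramer[lost] <- vapply(which(lost), function(i)
      .draw_variant_tetramer(cfg$deam_fraction), character(1))

  truth <- data.frame(site_id = sites$site_id, pos = as.integer(ann_pos),
                      m = m, efficiency = efficiency, gc_multiplier = gc_mult,
                      category = category, lost = lost,
                      variant_tetramer = variant_tetramer,
                      stringsAsFactors = FALSE)

  gained <- data.frame(pos = as.integer(gained_pos),
                       ref_tetramer = gained_ref,
                       m = stats::runif(length(gained_pos)),
                       efficiency = stats::rlnorm(length(gained_pos), 0,
                                                  cfg$efficiency_sigma),
                       stringsAsFactors = FALSE)

  # sampled individual: lost sites decayed, gained sites restored
  sbases <- bases
  if (any(lost)) {
    for (i in which(lost)) {
      idx <- (ann_pos[i] + 1L):(ann_pos[i] + 4L)
      sbases[idx] <- strsplit(variant_tetramer[i], "")[[1]]
    }
  }
  if (length(gained_pos)) {
    for (p in gained_pos) sbases[(p + 1L):(p + 4L)] <- c("C", "C", "G", "G")
  }
  sample_genome <- Biostrings::DNAStringSet(paste(sbases, collapse = ""))
  names(sample_genome) <- cfg$chrom_name

  structure(list(genome = genome, sampleGenome = sample_genome,
                 sites = sites, truth = truth, gained = gained,
                 islands = island_gr, repeats = repeat_gr, config = cfg),
            class = "HelpTagSim")
}

#' Simulate a HpaII or MspI tag library
#'
#' Generates 36-bp single-end reads from the sampled individual's
#' genome. Both flanks of every cut site yield reads; a read consists
#' of cut_length-1 bp of genomic flank ending at the cut, the CG
#' cohesive end, the CTGCTG remainder of the EcoP15I adapter, and
#' adapter filler, so the CGCTGCTG anchor begins at 1-based position
#' cut_length. The expected read count per flank is
#' Poisson(depth/2 x efficiency x lenFactor(fragment) x f), with
#' f = 1 - m for HpaII (only unmethylated molecules are cut) and f = 1
#' for MspI. Junk reads are random 36-mers guaranteed to lack the
#' anchor; substitution errors are applied at the configured rate.
#'
#' @param sim a `HelpTagSim` from [simulateGenome()].
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @param seed RNG seed for this library (defaults to the simulation
#'   seed + 1 for HpaII, + 2 for MspI).
#' @return list of class `HelpTagLibrary`: `reads` (named character
#'   vector of 36-bp sequences), `meta` (per-read truth: origin,
#'   site_id, pos, flank, cut_length), `expected` (per-site expected
#'   read counts), `enzyme`, `seed`.
#' @export
simulateLibrary <- function(sim, enzyme = c("HpaII", "MspI"), seed = NULL) {
  stopifnot(inherits(sim, "HelpTagSim"))
  if (length(enzyme) != 1L || !enzyme %in% c("HpaII", "MspI"))
    stop("enzyme must be \"HpaII\" or \"MspI\"", call. = FALSE)
  if (is.null(seed))
    seed <- sim$config$seed + if (enzyme == "HpaII") 1L else 2L
  withr::with_seed(as.integer(seed), .simulate_library_impl(sim, enzyme, seed))
}

.simulate_library_impl <- function(sim, enzyme, seed) {
  cfg <- sim$config
  L <- cfg$chrom_length
  truth <- sim$truth
  cut_tab <- data.frame(
    pos = c(truth$pos[!truth$lost], sim$gained$pos),
    m = c(truth$m[!truth$lost], sim$gained$m),
    eff = c(truth$efficiency[!truth$lost] * truth$gc_multiplier[!truth$lost],
            sim$gained$efficiency),
    site_id = c(truth$site_id[!truth$lost],
                rep(NA_integer_, nrow(sim$gained))),
    origin = c(rep("site", sum(!truth$lost)),
               rep("gained", nrow(sim$gained)))
  )
  cut_tab <- cut_tab[order(cut_tab$pos), , drop = FALSE]
  n <- nrow(cut_tab)
  cuts0 <- cut_tab$pos + 1L                    # 0-based cut coordinates
  bounds <- c(0L, cuts0, L)
  left_len <- diff(bounds)[seq_len(n)]         # fragment ending at each cut
  right_len <- diff(bounds)[seq_len(n) + 1L]
  meth_f <- if (enzyme == "HpaII") 1 - cut_tab$m else rep(1, n)
  lam <- 0.5 * cfg$depth * cut_tab$eff * meth_f
  lam_left <- lam * lenFactor(left_len, cfg$lenfactor_floor)
  lam_right <- lam * lenFactor(right_len, cfg$lenfactor_floor)

  n_left <- stats::rpois(n, lam_left)
  n_right <- stats::rpois(n, lam_right)

  chromstr <- as.character(sim$sampleGenome[[1]])
  cls <- as.integer(names(cfg$cut_length_probs))

  build_flank <- function(counts, flank) {
    idx <- rep.int(seq_len(n), counts)
    N <- length(idx)
    if (N == 0L)
      return(list(seq = character(0), idx = integer(0), cut = integer(0)))
    cut <- sample(cls, N, replace = TRUE, prob = cfg$cut_length_probs)
    p <- cut_tab$pos[idx]                      # 0-based site pos
    if (flank == "+") {
      lo <- p + 3L - cut; hi <- p + 3L         # 1-based window [lo, hi]
      gen <- substring(chromstr, lo, hi)
    } else {
      lo <- p + 2L; hi <- p + 2L + cut
      gen <- revcompChar(substring(chromstr, lo, hi))
    }
    reads <- paste0(gen, "CTGCTG",
                    substring(ADAPTER_FILLER, 1L, 29L - cut))
    list(seq = reads, idx = idx, cut = cut)
  }
  fl <- build_flank(n_left, "+")
  fr <- build_flank(n_right, "-")
  sig_seq <- c(fl$seq, fr$seq)
  sig_idx <- c(fl$idx, fr$idx)
  sig_cut <- c(fl$cut, fr$cut)
  sig_flank <- c(rep("+", length(fl$idx)), rep("-", length(fr$idx)))
  n_sig <- length(sig_seq)

  # substitution errors
  if (cfg$error_rate > 0 && n_sig > 0) {
    nerr <- stats::rbinom(n_sig, READ_LENGTH, cfg$error_rate)
    for (i in which(nerr > 0L)) {
      s <- strsplit(sig_seq[i], "")[[1]]
      at <- sample.int(READ_LENGTH, nerr[i])
      s[at] <- vapply(s[at], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
      sig_seq[i] <- paste(s, collapse = "")
    }
  }

  # junk reads: random 36-mers without the anchor motif
  n_junk <- if (cfg$junk_fraction > 0 && n_sig > 0)
    stats::rpois(1, n_sig * cfg$junk_fraction / (1 - cfg$junk_fraction)) else 0L
  junk_seq <- character(0)
  if (n_junk > 0L) {
    junk_seq <- vapply(seq_len(n_junk), function(i)
      paste(.rand_dna(READ_LENGTH, 0.5), collapse = ""), character(1))
    while (any(bad <- grepl(ANCHOR_MOTIF, junk_seq, fixed = TRUE))) {
      junk_seq[bad] <- vapply(seq_len(sum(bad)), function(i)
        paste(.rand_dna(READ_LENGTH, 0.5), collapse = ""), character(1))
    }
  }

  reads <- c(sig_seq, junk_seq)
  meta <- data.frame(
    origin = c(ifelse(cut_tab$origin[sig_idx] == "gained", "gained", "site"),
               rep("junk", n_junk)),
    site_id = c(cut_tab$site_id[sig_idx], rep(NA_integer_, n_junk)),
    pos = c(cut_tab$pos[sig_idx], rep(NA_integer_, n_junk)),
    flank = c(sig_flank, rep(NA_character_, n_junk)),
    cut_length = c(sig_cut, rep(NA_integer_, n_junk)),
    stringsAsFactors = FALSE
  )
  ord <- sample.int(length(reads))
  reads <- reads[ord]
  meta <- meta[ord, , drop = FALSE]
  ids <- sprintf("sim_%s_%06d", enzyme, seq_along(reads))
  names(reads) <- ids
  meta <- cbind(read_id = ids, meta)
  rownames(meta) <- NULL

  expected <- data.frame(site_id = cut_tab$site_id, pos = cut_tab$pos,
                         origin = cut_tab$origin,
                         expected_reads = lam_left + lam_right)
  if (any(truth$lost)) {
    expected <- rbind(expected,
      data.frame(site_id = truth$site_id[truth$lost],
                 pos = truth$pos[truth$lost], origin = "lost",
                 expected_reads = 0))
  }
  structure(list(reads = reads, meta = meta, expected = expected,
                 enzyme = enzyme, seed = seed),
            class = "HelpTagLibrary")
}

#' Write a simulated library as FASTQ
#'
#' Constant high base qualities are written; the pipeline's filters
#' are sequence-based and do not use qualities.
#'
#' @param lib a `HelpTagLibrary`.
#' @param path output FASTQ path; `.gz` suffix enables compression.
#' @return invisibly, the path.
#' @export
writeFastq <- function(lib, path) {
  reads <- Biostrings::DNAStringSet(lib$reads)
  qual <- Biostrings::PhredQuality(
    rep(strrep("I", READ_LENGTH), length(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(reads, qual)
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file as a named character vector of sequences
#'
#' The record structure is validated before parsing so that a
#' truncated or malformed file fails loudly rather than yielding a
#' silently shortened library.
#'
#' @param path FASTQ path (gzip allowed).
#' @return named character vector of read sequences.
#' @export
readFastq <- function(path) {
  con <- gzfile(path, "rt")
  lines <- readLines(con)
  close(con)
  if (length(lines) == 0L || length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines (not a multiple of 4)",
                 path, length(lines)), call. = FALSE)
  hdr <- lines[seq(1L, length(lines), 4L)]
  sep <- lines[seq(3L, length(lines), 4L)]
  if (!all(startsWith(hdr, "@")) || !all(startsWith(sep, "+")))
    stop(sprintf("malformed FASTQ '%s': bad record structure", path),
         call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
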