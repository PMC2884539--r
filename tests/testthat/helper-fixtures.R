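# Shared fixtures and independent oracles, built in code at load time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# one small simulation reused across test files
sim_small <- simulateGenome(simConfig(
  n_sites = 120L, chrom_length = 20000L, seed = 101L,
  n_repeat_copies = 4L))
lib_small_mspi <- simulateLibrary(sim_small, "MspI")

# GRanges of CCGG sites from 0-based positions
mk_sites <- function(pos0, chrom = "chr1", lens = NULL) {
  gr <- GRanges(rep(chrom, length(pos0)),
                IRanges::IRanges(pos0 + 1L, width = 4L),
                site_id = seq_along(pos0))
  if (!is.null(lens)) {
    GenomeInfoDb::seqlevels(gr) <- names(lens)
    GenomeInfoDb::seqlengths(gr) <- lens
  }
  gr
}

# naive sliding-window CCGG scan (independent of the package's
# vmatchPattern-based implementation); returns 0-based positions
oracle_ccgg <- function(seqstr) {
  s <- toupper(seqstr)
  n <- nchar(s)
  if (n < 4L) return(integer(0))
  starts <- 1:(n - 3L)
  which(substring(s, starts, starts + 3L) == "CCGG") - 1L
}

# per-base tally GC oracle; 0-based window [lo, hi)
oracle_gc <- function(seqstr, pos0, w = 50L) {
  lo <- max(pos0 + 2L - w %/% 2L, 0L)
  hi <- min(pos0 + 2L + w %/% 2L, nchar(seqstr))
  win <- strsplit(substr(seqstr, lo + 1L, hi), "")[[1]]
  win <- win[win != "N"]
  100 * sum(win %in% c("G", "C")) / length(win)
}

# exhaustive <=2-mismatch Hamming scan via Biostrings matchPattern,
# independent of the seed-and-extend implementation; N never matches.
oracle_align_one <- function(tag, chromstr, chrom = "chr1",
                             max_mismatch = 2L) {
  subj <- Biostrings::DNAString(chromstr)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") Biostrings::DNAString(tag)
           else Biostrings::reverseComplement(Biostrings::DNAString(tag))
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch, fixed = TRUE)
    if (length(m))
      out[[strand]] <- data.frame(
        chrom = chrom, start = start(m) - 1L, strand = strand,
        mismatches = vapply(seq_along(m), function(i)
          Biostrings::neditAt(pat, subj, at = start(m)[i], with.indels = FALSE),
          integer(1)),
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(0), start = integer(0),
                  strand = character(0), mismatches = integer(0))
}

# canonical string form of an alignment set, for set equality checks
aln_key <- function(df) {
  sort(sprintf("%s:%d:%s:%d", df$chrom, df$start, df$strand, df$mismatches))
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# introduce k substitutions into a sequence
mutate_seq <- function(s, k) {
  if (k == 0L) return(s)
  v <- strsplit(s, "")[[1]]
  at <- sample(length(v), k)
  for (i in at) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

# per-site realized read counts of a simulated library (truth side)
meta_site_counts <- function(lib, site_ids) {
  m <- lib$meta[lib$meta$origin == "site", ]
  as.numeric(table(factor(m$site_id, levels = site_ids)))
}
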