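#' Find all CCGG sites in a genome
#'
#' Scans every sequence of a genome for occurrences of the HpaII/MspI
#' recognition tetramer CCGG. CCGG is its own reverse complement, so a
#' single record per occurrence represents both strands. Soft-masked
#' (lowercase) bases are treated as their uppercase equivalents.
#'
#' @param genome a [Biostrings::DNAStringSet] (named), a character
#'   vector of sequences, or the path to a FASTA file (gzip allowed).
#' @return a [GenomicRanges::GRanges] with one width-4 range per CCGG
#'   occurrence, sorted by chromosome (in genome order) then position,
#'   carrying a `site_id` metadata column (1-based stable index) and
#'   the genome's `seqlengths`. The 0-based position of the first C is
#'   `start(x) - 1`.
#' @examples
#' findCCGGSites(c(chr1 = "ACCGGT"))
#' @export
findCCGGSites <- function(genome) {
  genome <- .as_genome(genome)
  if (length(genome) == 0L) {
    return(GRanges(site_id = integer(0)))
  }
  hits <- Biostrings::vmatchPattern("CCGG", genome, fixed = TRUE)
  per_chrom <- lapply(seq_along(genome), function(i) {
    ir <- hits[[i]]
    GRanges(names(genome)[i], ir)
  })
  gr <- sort(do.call(c, per_chrom), ignore.strand = TRUE)
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
  gr$site_id <- seq_along(gr)
  gr
}

# Normalize genome input to an uppercase named DNAStringSet and check
# the alphabet, reporting the first offending character and position.
.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("seq", seq_along(genome))
    for (i in seq_along(genome))
      .check_dna_chars(genome[i], names(genome)[i])
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet, character vector or FASTA path",
         call. = FALSE)
  if (length(genome) == 0L) return(genome)
  if (is.null(names(genome)))
    stop("genome sequences must be named", call. = FALSE)
  freq <- Biostrings::alphabetFrequency(genome)
  allowed <- c("A", "C", "G", "T", "N")
  extra <- freq[, setdiff(colnames(freq), allowed), drop = FALSE]
  if (any(extra > 0)) {
    i <- which(rowSums(extra) > 0)[1L]
    s <- as.character(genome[[i]])
    bad <- regexpr("[^ACGTN]", s)
    stop(sprintf("non-DNA character '%s' at position %d of %s",
                 substr(s, bad, bad), bad, names(genome)[i]), call. = FALSE)
  }
  genome
}

#' Virtual restriction digestion
#'
#' Places a cut between the first and second base of every CCGG site
#' (HpaII/MspI cut C^CGG) and returns the resulting fragments. The
#' fragments of each chromosome partition it exactly: no gaps, no
#' overlaps, lengths summing to the chromosome length.
#'
#' @param sites GRanges of CCGG sites as from [findCCGGSites()].
#' @param chrom_lengths named integer vector of chromosome lengths;
#'   defaults to `seqlengths(sites)`.
#' @return GRanges of fragments with a `length` metadata column.
#' @export
virtualDigest <- function(sites, chrom_lengths = GenomeInfoDb::seqlengths(sites)) {
  if (any(is.na(chrom_lengths)))
    stop("chrom_lengths must be defined for every chromosome", call. = FALSE)
  chroms <- names(chrom_lengths)
  site_chrom <- as.character(seqnames(sites))
  if (!all(site_chrom %in% chroms))
    stop("sites on chromosomes missing from chrom_lengths: ",
         paste(setdiff(site_chrom, chroms), collapse = ", "), call. = FALSE)
  frags <- lapply(chroms, function(ch) {
    L <- chrom_lengths[[ch]]
    pos <- start(sites)[site_chrom == ch] - 1L  # 0-based first C
    if (any(pos + 4L > L))
      stop(sprintf("site at %s:%d extends beyond chromosome length %d",
                   ch, max(pos), L), call. = FALSE)
    cuts <- sort(pos) + 1L                      # 0-based cut coordinate
    b <- c(0L, cuts, L)
    GRanges(ch, IRanges::IRanges(start = b[-length(b)] + 1L, end = b[-1L]))
  })
  out <- do.call(c, frags)
  GenomeInfoDb::seqlevels(out) <- chroms
  GenomeInfoDb::seqlengths(out) <- chrom_lengths
  out$length <- width(out)
  out
}

#' Local GC composition around CCGG sites
#'
#' Percent G+C in a window centered on the midpoint of the CCGG
#' tetramer (0-based pos + 2). N bases are excluded from both the
#' numerator and the denominator; windows clipped at chromosome ends
#' use the available bases, with the effective length recorded.
#'
#' @param genome genome as accepted by [findCCGGSites()].
#' @param sites GRanges of CCGG sites.
#' @param window_bp window width in bp; must be even and >= 4.
#'   Default 50, i.e. a 50-bp region centered at the restriction site.
#' @return data.frame with columns site_id, gc_percent, window_len.
#'   A full-length window always contains the CCGG tetramer, so
#'   gc_percent lies in [8, 100] when window_bp = 50.
#' @export
gcWindows <- function(genome, sites, window_bp = 50L) {
  if (window_bp %% 2L != 0L || window_bp < 4L)
    stop("window_bp must be even and >= 4", call. = FALSE)
  genome <- .as_genome(genome)
  half <- window_bp %/% 2L
  pos <- start(sites) - 1L                      # 0-based
  chrom <- as.character(seqnames(sites))
  out <- data.frame(site_id = sites$site_id,
                    gc_percent = NA_real_, window_len = NA_integer_)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    L <- Biostrings::width(genome)[match(ch, names(genome))]
    lo <- pmax(pos[idx] + 2L - half + 1L, 1L)   # 1-based
    hi <- pmin(pos[idx] + 2L + half, L)
    v <- Biostrings::Views(genome[[match(ch, names(genome))]], start = lo, end = hi)
    lf <- Biostrings::letterFrequency(v, letters = c("G", "C", "N"))
    eff <- (hi - lo + 1L) - lf[, "N"]
    out$gc_percent[idx] <- ifelse(eff > 0, 100 * (lf[, "G"] + lf[, "C"]) / eff, NA_real_)
    out$window_len[idx] <- hi - lo + 1L
  }
  out
}

#' Export CCGG sites or fragments as BED4
#'
#' BED output is 0-based half-open per the format convention.
#'
#' @param x GRanges of sites (name column taken from site_id) or
#'   fragments.
#' @param path output file.
#' @return invisibly, the path.
#' @export
exportBED <- function(x, path) {
  df <- data.frame(
    chrom = as.character(seqnames(x)),
    start = start(x) - 1L,
    end = end(x),
    name = if (!is.null(x$site_id)) x$site_id else seq_along(x)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
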