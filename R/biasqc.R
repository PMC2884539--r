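# Systematic-bias diagnostics. MspI counts are methylation-blind, so
# comparing their distribution across GC or fragment-length bins with
# the genomic distribution of sites/fragments exposes assay biases.

#' GC-composition representation of sequenced tags
#'
#' Compares the observed fractional read weight across 2% GC bins of
#' the 50-bp windows around sites with the genomic expectation (the
#' fraction of sites per bin). Fifty sequential non-overlapping bins
#' [0,2), [2,4), ..., [98,100] cover the domain; both proportion
#' columns sum to 1.
#'
#' @param counts a [SiteCounts-class] object.
#' @param gcwindows data.frame from [gcWindows()] over the same site
#'   universe.
#' @return data.frame: bin_lo, bin_hi, expected_prop, observed_prop,
#'   ratio (observed/expected, NA where no sites fall in a bin).
#' @export
gcRepresentation <- function(counts, gcwindows) {
  stopifnot(methods::is(counts, "SiteCounts"))
  gc <- gcwindows$gc_percent[match(counts@sites$site_id, gcwindows$site_id)]
  if (any(is.na(gc)))
    stop("gcwindows must cover every site in counts", call. = FALSE)
  tot <- sum(counts@counts)
  if (tot == 0)
    stop("empty counts: no read weight to compare", call. = FALSE)
  bin <- pmin(floor(gc / 2), 49) + 1L
  expected <- tabulate(bin, nbins = 50L) / length(bin)
  obs_w <- rowsum(counts@counts, group = bin)
  observed <- numeric(50L)
  observed[as.integer(rownames(obs_w))] <- obs_w[, 1]
  observed <- observed / tot
  data.frame(bin_lo = seq(0, 98, 2), bin_hi = seq(2, 100, 2),
             expected_prop = expected, observed_prop = observed,
             ratio = ifelse(expected > 0, observed / expected, NA_real_))
}

#' Fragment-length representation of sequenced tags
#'
#' Compares observed read weight per restriction-fragment length bin
#' with the virtual-digest expectation (fraction of fragments per
#' bin). A read's weight accrues to the fragment containing its tag
#' span: plus-strand alignments of a site lie in the fragment ending
#' at the site's cut, minus-strand alignments in the fragment starting
#' there. Length bins are 25-bp steps to 1,000 bp, then open-ended.
#'
#' @param counts a [SiteCounts-class] object carrying assignment
#'   detail (as produced by [assignToSites()]). Without detail, each
#'   site's weight is split evenly between its two abutting fragments.
#' @param fragments GRanges from [virtualDigest()].
#' @return data.frame: bin, expected_prop, observed_prop, ratio.
#' @export
fragmentRepresentation <- function(counts, fragments) {
  stopifnot(methods::is(counts, "SiteCounts"))
  breaks <- c(seq(0, 1000, 25), Inf)
  labs <- c(sprintf("(%d,%d]", seq(0, 975, 25), seq(25, 1000, 25)), ">1000")
  flen <- width(fragments)
  fbin <- cut(flen, breaks = breaks, labels = labs)
  expected <- as.numeric(table(fbin)) / length(fbin)

  fch <- as.character(seqnames(fragments))
  left_key <- paste(fch, end(fragments))      # fragment ending at cut p+1
  right_key <- paste(fch, start(fragments))   # fragment starting at p+2

  sch <- as.character(seqnames(counts@sites))
  pos0 <- start(counts@sites) - 1L
  a <- counts@assignments
  if (nrow(a)) {
    si <- match(a$site_id, counts@sites$site_id)
    key <- ifelse(a$strand == "+",
                  paste(sch[si], pos0[si] + 1L),
                  paste(sch[si], pos0[si] + 2L))
    fi <- ifelse(a$strand == "+",
                 match(key, left_key), match(key, right_key))
    w <- a$weight
  } else {
    fi <- c(match(paste(sch, pos0 + 1L), left_key),
            match(paste(sch, pos0 + 2L), right_key))
    w <- rep(counts@counts / 2, 2L)
  }
  ok <- !is.na(fi)
  tot <- sum(w[ok])
  if (tot == 0)
    stop("empty counts: no read weight to compare", call. = FALSE)
  wbin <- rowsum(w[ok], group = as.integer(fbin)[fi[ok]])
  observed <- numeric(length(labs))
  observed[as.integer(rownames(wbin))] <- wbin[, 1]
  observed <- observed / tot
  data.frame(bin = labs, expected_prop = expected,
             observed_prop = observed,
             ratio = ifelse(expected > 0, observed / expected, NA_real_))
}
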