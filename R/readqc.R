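#' Locate the adapter anchor in reads
#'
#' Genuine reads carry a 5'-CGCTGCTG sequence toward their 3' end: the
#' CG cohesive end of the HpaII/MspI cut followed by the EcoP15I
#' recognition site of the ligated adapter. The leftmost exact
#' occurrence is reported; no mismatches are tolerated in the 8-mer.
#'
#' @param sequences character vector of read sequences.
#' @return integer vector of 1-based anchor start positions, NA where
#'   the motif is absent.
#' @examples
#' findAnchor(c("CGCTGCTGAAAA", "AAAA"))
#' @export
findAnchor <- function(sequences) {
  if (any(!nzchar(sequences)))
    stop("sequences must be non-empty", call. = FALSE)
  p <- regexpr(ANCHOR_MOTIF, sequences, fixed = TRUE)
  ifelse(p > 0L, as.integer(p), NA_integer_)
}

#' Extract the 27-bp tag from an anchored read
#'
#' The adapter portion of the read (everything from two bases past the
#' anchor start, i.e. after the genomic CG cohesive end) is replaced by
#' N, and the tag is the masked bases 2-28 (1-based, inclusive). The
#' result is always exactly 27 bp; trailing Ns mark adapter-derived
#' positions that must not count as genomic sequence.
#'
#' @param sequences character vector of read sequences.
#' @param anchor_pos integer vector of anchor positions as returned by
#'   [findAnchor()]; NA entries raise an error (filter first).
#' @return character vector of 27-bp tags.
#' @export
extractTag <- function(sequences, anchor_pos = findAnchor(sequences)) {
  if (any(is.na(anchor_pos)))
    stop("cannot extract a tag from a read without an anchor; filter first",
         call. = FALSE)
  tag <- substr(sequences, 2L, 28L)
  # read positions >= anchor_pos + 2 are adapter; in tag coordinates the
  # mask starts at anchor_pos + 1
  mask_from <- pmax(anchor_pos + 1L, 1L)
  needs <- mask_from <= TAG_LENGTH
  n_mask <- pmax(TAG_LENGTH - mask_from + 1L, 0L)
  tag[needs] <- paste0(substr(tag[needs], 1L, mask_from[needs] - 1L),
                       strrep("N", n_mask[needs]))
  if (any(nchar(tag) != TAG_LENGTH))
    stop("reads shorter than 28 bp cannot yield a 27-bp tag", call. = FALSE)
  tag
}

#' Partition reads on anchor presence
#'
#' @param reads named character vector of read sequences.
#' @return list with elements `kept` (anchored reads), `discarded`,
#'   and `anchor_pos` (positions for the kept reads).
#' @export
filterReads <- function(reads) {
  ap <- findAnchor(reads)
  keep <- !is.na(ap)
  list(kept = reads[keep], discarded = reads[!keep], anchor_pos = ap[keep])
}

#' Read-level quality report
#'
#' Summarizes a library: total reads, reads carrying the adapter
#' anchor (count and fraction), the positional histogram of anchor
#' starts, and the number and position of ambiguous (N) base calls.
#'
#' @param reads character vector of read sequences.
#' @return list of class `QCReport`: `total`, `anchored`,
#'   `fraction_with_anchor`, `anchor_pos_hist` (named integer vector),
#'   `n_count_hist` (reads by number of Ns), `n_pos_hist` (N calls by
#'   read position).
#' @export
qcReport <- function(reads) {
  if (length(reads) == 0L) {
    warning("qcReport called on zero reads")
    out <- list(total = 0L, anchored = 0L, fraction_with_anchor = NaN,
                anchor_pos_hist = integer(0),
                n_count_hist = integer(0), n_pos_hist = integer(0))
    class(out) <- "QCReport"
    return(out)
  }
  ap <- findAnchor(reads)
  anchored <- sum(!is.na(ap))
  pos_hist <- table(ap[!is.na(ap)])
  n_per_read <- vapply(gregexpr("N", reads, fixed = TRUE), function(g)
    if (g[1] == -1L) 0L else length(g), integer(1))
  n_pos <- unlist(lapply(gregexpr("N", reads, fixed = TRUE), function(g)
    if (g[1] == -1L) integer(0) else as.integer(g)))
  out <- list(total = length(reads), anchored = anchored,
              fraction_with_anchor = anchored / length(reads),
              anchor_pos_hist = pos_hist,
              n_count_hist = table(n_per_read),
              n_pos_hist = if (length(n_pos)) table(n_pos) else integer(0))
  class(out) <- "QCReport"
  out
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QC report: %d reads, %d with anchor (%s)\n",
              x$total, x$anchored,
              if (x$total) .pct(x$fraction_with_anchor) else "NA"))
  if (length(x$anchor_pos_hist)) {
    mode_pos <- names(x$anchor_pos_hist)[which.max(x$anchor_pos_hist)]
    cat(sprintf("  anchor-position mode: %s\n", mode_pos))
  }
  if (length(x$n_count_hist))
    cat(sprintf("  reads without N: %s\n",
                .pct(sum(x$n_count_hist[names(x$n_count_hist) == "0"]) /
                       max(x$total, 1L))))
  invisible(x)
}

#' Write a QC report as TSV
#' @param x a `QCReport`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeQCReport <- function(x, path) {
  lines <- c(
    sprintf("total\t%d", x$total),
    sprintf("anchored\t%d", x$anchored),
    sprintf("fraction_with_anchor\t%.6g", x$fraction_with_anchor),
    sprintf("anchor_pos\t%s\t%d", names(x$anchor_pos_hist),
            as.integer(x$anchor_pos_hist)),
    sprintf("n_count\t%s\t%d", names(x$n_count_hist),
            as.integer(x$n_count_hist)),
    if (length(x$n_pos_hist))
      sprintf("n_pos\t%s\t%d", names(x$n_pos_hist),
              as.integer(x$n_pos_hist))
  )
  writeLines(lines, path)
  invisible(path)
}
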