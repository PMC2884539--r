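#' Construct a SiteCounts object
#'
#' @param sites GRanges of CCGG sites with site_id.
#' @param counts numeric per-site fractional counts.
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @param nRetained reads carrying weight in this table.
#' @param dropped data.frame(reason, reads).
#' @param assignments,unassigned per-alignment detail (may be empty).
#' @return a [SiteCounts-class] object.
#' @export
SiteCounts <- function(sites, counts, enzyme,
                       nRetained = sum(counts),
                       dropped = data.frame(reason = character(0),
                                            reads = numeric(0)),
                       assignments = data.frame(),
                       unassigned = data.frame()) {
  methods::new("SiteCounts", sites = sites, counts = as.numeric(counts),
               enzyme = enzyme, nRetained = as.numeric(nRetained),
               dropped = dropped, assignments = assignments,
               unassigned = unassigned)
}

# first non-NA across ordered candidate columns
.first_match <- function(mat) {
  idx <- rep(NA_integer_, nrow(mat))
  for (j in seq_len(ncol(mat))) {
    fill <- is.na(idx) & !is.na(mat[, j])
    idx[fill] <- mat[fill, j]
  }
  idx
}

#' Assign tag alignments to CCGG sites with fractional weights
#'
#' An alignment is assigned to a site when its cut-proximal end
#' coincides with the site's central CG within a small slack that
#' absorbs the 25-27 bp EcoP15I cut-length variation. For a plus-strand
#' alignment starting at 0-based `t` the nominal site position is
#' `t + 24`; for a minus-strand alignment it is `t - 1`. Candidate
#' offsets are tried in the order 0, -1, +1, -2, +2 (exact first, then
#' smaller distance, then lower coordinate). Each alignment contributes
#' 1/n_hits; alignments adjacent to no site are returned in the
#' unassigned slot and feed [detectGainedSites()]. Both flanks of a
#' site aggregate into a single per-site count.
#'
#' @param alignments data.frame from [alignTags()]`$alignments` (or
#'   the full list, in which case the dropped tally is carried over).
#' @param sites GRanges of annotated CCGG sites.
#' @param enzyme `"HpaII"` or `"MspI"` label for the resulting table.
#' @param slack maximum distance, bp (default 2).
#' @param dropped optional data.frame of dropped reads from the
#'   aligner, tallied into the result.
#' @return a [SiteCounts-class] object.
#' @export
assignToSites <- function(alignments, sites, enzyme = "MspI", slack = 2L,
                          dropped = NULL) {
  if (is.list(alignments) && !is.data.frame(alignments) &&
      all(c("alignments", "dropped") %in% names(alignments))) {
    dropped <- alignments$dropped
    alignments <- alignments$alignments
  }
  drop_tally <- if (!is.null(dropped) && nrow(dropped)) {
    stats::aggregate(list(reads = dropped$read_id),
                     by = list(reason = dropped$reason),
                     FUN = function(x) length(unique(x)))
  } else data.frame(reason = character(0), reads = numeric(0))

  n_aln <- nrow(alignments)
  site_key <- paste(as.character(seqnames(sites)), start(sites) - 1L)
  counts <- numeric(length(sites))
  if (n_aln == 0L) {
    return(SiteCounts(sites, counts, enzyme, nRetained = 0,
                      dropped = drop_tally))
  }
  implied <- ifelse(alignments$strand == "+",
                    alignments$start + 24L, alignments$start - 1L)
  offsets <- c(0L, -1L, 1L)
  if (slack >= 2L) offsets <- c(offsets, -2L, 2L)
  offsets <- offsets[abs(offsets) <= slack]
  mat <- vapply(offsets, function(d)
    match(paste(alignments$chrom, implied + d), site_key), integer(n_aln))
  if (n_aln == 1L) mat <- matrix(mat, nrow = 1L)
  site_idx <- .first_match(mat)
  weight <- 1 / alignments$n_hits

  assigned <- !is.na(site_idx)
  if (any(assigned)) {
    agg <- rowsum(weight[assigned], group = site_idx[assigned])
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  a_df <- cbind(alignments[assigned, , drop = FALSE],
                site_id = sites$site_id[site_idx[assigned]],
                weight = weight[assigned],
                implied_pos = implied[assigned])
  u_df <- cbind(alignments[!assigned, , drop = FALSE],
                weight = weight[!assigned],
                implied_pos = implied[!assigned])
  rownames(a_df) <- rownames(u_df) <- NULL
  SiteCounts(sites, counts, enzyme,
             nRetained = length(unique(alignments$read_id)),
             dropped = drop_tally, assignments = a_df, unassigned = u_df)
}

#' Count one enzyme library end-to-end
#'
#' Convenience wrapper: anchor filtering, tag extraction, alignment
#' and fractional site assignment.
#'
#' @param reads named character vector of read sequences (or a
#'   `HelpTagLibrary`).
#' @param genome genome as accepted by [findCCGGSites()].
#' @param sites GRanges of annotated CCGG sites.
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @param max_mismatch,max_hits,slack see [alignTags()] and
#'   [assignToSites()].
#' @return a [SiteCounts-class] object.
#' @export
countLibrary <- function(reads, genome, sites, enzyme,
                         max_mismatch = 2L, max_hits = 10L, slack = 2L) {
  if (inherits(reads, "HelpTagLibrary")) {
    if (!missing(enzyme) && enzyme != reads$enzyme)
      warning("enzyme argument differs from the library's enzyme")
    if (missing(enzyme)) enzyme <- reads$enzyme
    reads <- reads$reads
  }
  f <- filterReads(reads)
  tags <- extractTag(f$kept, f$anchor_pos)
  names(tags) <- names(f$kept)
  al <- alignTags(tags, genome, max_mismatch = max_mismatch,
                  max_hits = max_hits)
  assignToSites(al$alignments, sites, enzyme = enzyme, slack = slack,
                dropped = al$dropped)
}

.check_same_universe <- function(a, b) {
  if (length(a@sites) != length(b@sites) ||
      !identical(a@sites$site_id, b@sites$site_id) ||
      !identical(start(a@sites), start(b@sites)) ||
      !identical(as.character(seqnames(a@sites)),
                 as.character(seqnames(b@sites)))) {
    off <- union(setdiff(a@sites$site_id, b@sites$site_id),
                 setdiff(b@sites$site_id, a@sites$site_id))
    stop("site universes differ",
         if (length(off)) paste0(": offending site_ids ",
                                 paste(utils::head(off, 10), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Merge sequencing lanes of one enzyme
#'
#' Element-wise sum of fractional counts over identical site
#' universes, applied before any fixed-count normalization (merging
#' then fixing equals fixing the sums).
#'
#' @param ... two or more [SiteCounts-class] objects (or a list).
#' @return a merged [SiteCounts-class] object.
#' @export
mergeLanes <- function(...) {
  lanes <- list(...)
  if (length(lanes) == 1L && is.list(lanes[[1]]) &&
      !methods::is(lanes[[1]], "SiteCounts"))
    lanes <- lanes[[1]]
  stopifnot(length(lanes) >= 1L)
  out <- lanes[[1]]
  if (length(lanes) == 1L) return(out)
  for (x in lanes[-1]) {
    .check_same_universe(out, x)
    if (out@enzyme != x@enzyme)
      stop("cannot merge lanes of different enzymes", call. = FALSE)
    out@counts <- out@counts + x@counts
    out@nRetained <- out@nRetained + x@nRetained
    out@dropped <- if (nrow(out@dropped) || nrow(x@dropped)) {
      d <- rbind(out@dropped, x@dropped)
      stats::aggregate(reads ~ reason, data = d, FUN = sum)
    } else out@dropped
    if (nrow(x@assignments))
      out@assignments <- rbind(out@assignments, x@assignments)
    if (nrow(x@unassigned))
      out@unassigned <- rbind(out@unassigned, x@unassigned)
  }
  methods::validObject(out)
  out
}

#' Pearson correlation between replicate count tables
#'
#' Computed on the raw fractional counts over the shared site
#' universe; a site with no reads in a sample counts 0 there.
#'
#' @param a,b [SiteCounts-class] objects over the same site universe.
#' @return Pearson correlation coefficient.
#' @export
replicateCorrelation <- function(a, b) {
  .check_same_universe(a, b)
  if (stats::sd(a@counts) == 0)
    stop("first sample has zero variance; correlation undefined",
         call. = FALSE)
  if (stats::sd(b@counts) == 0)
    stop("second sample has zero variance; correlation undefined",
         call. = FALSE)
  stats::cor(a@counts, b@counts)
}

#' Site coverage summary
#'
#' @param x a [SiteCounts-class] object.
#' @return list with `fraction_covered` (sites with >= 1 fractional
#'   read... strictly, with any positive weight) and `mean_reads`
#'   (mean fractional reads per site).
#' @export
coverageSummary <- function(x) {
  stopifnot(methods::is(x, "SiteCounts"))
  n <- length(x@counts)
  list(fraction_covered = if (n) mean(x@counts > 0) else 0,
       mean_reads = if (n) mean(x@counts) else 0)
}

#' Write a count table (with fixed counts) as TSV
#'
#' @param x a [SiteCounts-class] object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCounts <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [writeCounts()]
#'
#' @param path TSV path.
#' @param enzyme enzyme label for the reconstructed object.
#' @return a [SiteCounts-class] object (assignment detail not
#'   preserved).
#' @export
readCounts <- function(path, enzyme) {
  df <- utils::read.delim(path)
  gr <- GRanges(df$chrom, IRanges::IRanges(df$pos + 1L, width = 4L),
                site_id = df$site_id)
  SiteCounts(gr, df$count, enzyme, nRetained = sum(df$count))
}
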