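# Internal tag aligner: exhaustive seed-and-extend.
#
# Tags are 27-mers aligned with at most 2 mismatches (N counts as a
# mismatch on either side). Three 9-bp seeds at tag offsets 0/9/18 are
# looked up in an exact k-mer index of the genome; with <= 2 mismatches
# at least one of three disjoint seeds is mismatch-free (pigeonhole),
# so candidate extension with plain Hamming verification is complete.

.SEED_K <- 9L
.RAW_N <- charToRaw("N")

.build_seed_index <- function(chromstr, k = .SEED_K) {
  L <- nchar(chromstr)
  if (L < k) return(list(keys = character(0), pos = list()))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(chromstr, starts, starts + k - 1L)
  idx <- split(starts, kmers)
  list(keys = names(idx), pos = idx)
}

# Hamming mismatches of traw (length 27 raw) against graw at 1-based
# candidate starts; Ns mismatch everything.
.verify_candidates <- function(graw, traw, starts) {
  n_t <- traw == .RAW_N
  vapply(starts, function(s) {
    g <- graw[s:(s + TAG_LENGTH - 1L)]
    sum(g != traw | n_t | g == .RAW_N)
  }, integer(1))
}

#' Align 27-bp tags to a genome
#'
#' Reports every genomic location, on either strand, where a tag
#' matches with at most `max_mismatch` mismatches; N positions count
#' as mismatches. Tags with no location are dropped as unalignable,
#' tags with more than `max_hits` locations are dropped as too
#' repetitive, and tags carrying more than 2 Ns within their first 25
#' bases are dropped before alignment (their mismatch budget is
#' already spent). Every surviving alignment records `n_hits`, the
#' total number of locations of its tag, used for fractional (1/n)
#' counting downstream.
#'
#' @param tags character vector of 27-bp tags; names are read ids
#'   (defaults to tag_1, tag_2, ...). Duplicate sequences are aligned
#'   once and expanded.
#' @param genome genome as accepted by [findCCGGSites()].
#' @param max_mismatch maximum mismatches per alignment (default 2).
#' @param max_hits maximum alignment locations per tag (default 10).
#' @return list with `alignments` (data.frame: read_id, tag, chrom,
#'   start 0-based, strand, mismatches, n_hits) and `dropped`
#'   (data.frame: read_id, tag, reason).
#' @export
alignTags <- function(tags, genome, max_mismatch = 2L, max_hits = 10L) {
  if (length(tags) && any(nchar(tags) != TAG_LENGTH))
    stop("all tags must be exactly 27 bp", call. = FALSE)
  if (is.null(names(tags)))
    names(tags) <- sprintf("tag_%d", seq_along(tags))
  genome <- .as_genome(genome)
  chromstrs <- as.character(genome)

  empty_aln <- data.frame(read_id = character(0), tag = character(0),
                          chrom = character(0), start = integer(0),
                          strand = character(0), mismatches = integer(0),
                          n_hits = integer(0), stringsAsFactors = FALSE)
  empty_drop <- data.frame(read_id = character(0), tag = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  if (length(tags) == 0L)
    return(list(alignments = empty_aln, dropped = empty_drop))

  uniq <- unique(unname(tags))
  n_head <- vapply(gregexpr("N", substr(uniq, 1L, 25L), fixed = TRUE),
                   function(g) if (g[1] == -1L) 0L else length(g), integer(1))
  ambiguous <- n_head > 2L

  seed_off <- c(0L, 9L, 18L)
  fwd_seeds <- vapply(seed_off, function(o)
    substr(uniq, o + 1L, o + .SEED_K), character(length(uniq)))
  rc_uniq <- revcompChar(uniq)
  rc_seeds <- vapply(seed_off, function(o)
    substr(rc_uniq, o + 1L, o + .SEED_K), character(length(uniq)))
  if (length(uniq) == 1L) {
    fwd_seeds <- matrix(fwd_seeds, nrow = 1L)
    rc_seeds <- matrix(rc_seeds, nrow = 1L)
  }

  acc <- list(); k <- 0L
  for (ci in seq_along(chromstrs)) {
    chrom <- names(genome)[ci]
    cs <- chromstrs[[ci]]
    L <- nchar(cs)
    if (L < TAG_LENGTH) next
    index <- .build_seed_index(cs)
    graw <- charToRaw(cs)
    fmatch <- matrix(match(fwd_seeds, index$keys), nrow = length(uniq))
    rmatch <- matrix(match(rc_seeds, index$keys), nrow = length(uniq))
    for (ti in which(!ambiguous)) {
      for (strand in c("+", "-")) {
        mrow <- if (strand == "+") fmatch[ti, ] else rmatch[ti, ]
        if (all(is.na(mrow))) next
        cand <- integer(0)
        for (j in seq_along(seed_off)) {
          if (is.na(mrow[j])) next
          cand <- c(cand, index$pos[[mrow[j]]] - seed_off[j])
        }
        cand <- unique(cand)
        cand <- cand[cand >= 1L & cand + TAG_LENGTH - 1L <= L]
        if (!length(cand)) next
        traw <- charToRaw(if (strand == "+") uniq[ti] else rc_uniq[ti])
        mm <- .verify_candidates(graw, traw, cand)
        ok <- mm <= max_mismatch
        if (any(ok)) {
          k <- k + 1L
          acc[[k]] <- list(ti = ti, chrom = chrom, start = cand[ok] - 1L,
                           strand = strand, mm = mm[ok])
        }
      }
    }
  }

  if (k > 0L) {
    nrec <- vapply(acc, function(a) length(a$start), integer(1))
    uhits <- data.frame(
      ti = rep(vapply(acc, `[[`, integer(1), "ti"), nrec),
      chrom = rep(vapply(acc, `[[`, character(1), "chrom"), nrec),
      start = as.integer(unlist(lapply(acc, `[[`, "start"))),
      strand = rep(vapply(acc, `[[`, character(1), "strand"), nrec),
      mismatches = as.integer(unlist(lapply(acc, `[[`, "mm"))),
      stringsAsFactors = FALSE)
  } else {
    uhits <- data.frame(ti = integer(0), chrom = character(0),
                        start = integer(0), strand = character(0),
                        mismatches = integer(0), stringsAsFactors = FALSE)
  }
  uhits <- uhits[order(uhits$ti), , drop = FALSE]
  n_hits_u <- tabulate(uhits$ti, nbins = length(uniq))
  reason_u <- rep(NA_character_, length(uniq))
  reason_u[ambiguous] <- "ambiguous_bases"
  reason_u[!ambiguous & n_hits_u == 0L] <- "no_alignment"
  reason_u[!ambiguous & n_hits_u > max_hits] <- "too_many_hits"

  tag_idx <- match(unname(tags), uniq)
  keep_read <- is.na(reason_u)[tag_idx]

  aln <- empty_aln
  if (any(keep_read)) {
    first_row <- integer(length(uniq))
    fr <- which(!duplicated(uhits$ti))
    first_row[uhits$ti[fr]] <- fr
    kr <- which(keep_read)
    nv <- n_hits_u[tag_idx[kr]]
    rows <- sequence(nv, from = first_row[tag_idx[kr]])
    aln <- data.frame(
      read_id = rep(names(tags)[kr], nv),
      tag = rep(unname(tags[kr]), nv),
      chrom = uhits$chrom[rows],
      start = uhits$start[rows],
      strand = uhits$strand[rows],
      mismatches = uhits$mismatches[rows],
      n_hits = rep(nv, nv),
      stringsAsFactors = FALSE)
  }
  dropped <- empty_drop
  if (any(!keep_read)) {
    dropped <- data.frame(read_id = names(tags)[!keep_read],
                          tag = unname(tags[!keep_read]),
                          reason = reason_u[tag_idx[!keep_read]],
                          stringsAsFactors = FALSE)
  }
  list(alignments = aln, dropped = dropped)
}

#' Import tag alignments from SAM
#'
#' Accepts alignments from an external aligner as an alternative to
#' [alignTags()]. The NM tag provides the mismatch count and the NH
#' tag the number of alignment locations; when NH is absent, records
#' sharing a read id are collapsed to derive it. The same retention
#' rules as the internal aligner are applied (mismatches <= 2, at most
#' `max_hits` locations).
#'
#' @param path a SAM (or BAM) file.
#' @param max_mismatch,max_hits retention thresholds.
#' @return list with `alignments` and `dropped`, as [alignTags()].
#' @export
readTagAlignmentsSAM <- function(path, max_mismatch = 2L, max_hits = 10L) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq"),
    tag = c("NM", "NH"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(b$pos)
  df <- data.frame(read_id = b$qname[mapped],
                   tag = as.character(b$seq)[mapped],
                   chrom = as.character(b$rname)[mapped],
                   start = b$pos[mapped] - 1L,
                   strand = as.character(b$strand)[mapped],
                   mismatches = if (!is.null(b$tag$NM))
                     b$tag$NM[mapped] else 0L,
                   stringsAsFactors = FALSE)
  df <- df[df$mismatches <= max_mismatch, , drop = FALSE]
  nh <- table(df$read_id)
  df$n_hits <- as.integer(nh[df$read_id])
  if (!is.null(b$tag$NH)) {
    nh_tag <- b$tag$NH[mapped]
    df$n_hits <- pmax(df$n_hits, nh_tag[match(df$read_id, b$qname[mapped])])
  }
  drop_ids <- unique(df$read_id[df$n_hits > max_hits])
  unmapped_ids <- setdiff(unique(b$qname), df$read_id)
  dropped <- data.frame(
    read_id = c(unmapped_ids, drop_ids),
    tag = NA_character_,
    reason = c(rep("no_alignment", length(unmapped_ids)),
               rep("too_many_hits", length(drop_ids))),
    stringsAsFactors = FALSE)
  list(alignments = df[df$n_hits <= max_hits, , drop = FALSE],
       dropped = dropped)
}
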