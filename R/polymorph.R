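# Polymorphic CCGG discovery: annotated sites with zero MspI evidence
# (destroyed by a variant in the sequenced individual) and unannotated
# loci with clustered MspI evidence (created by a variant).

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a single-base CCGG substitution
#'
#' Produces the canonical, strand-folded base-pair substitution string
#' for a tetramer differing from CCGG at exactly one position: a C->T
#' on the plus strand and its G->A counterpart on the minus strand
#' both report `"C:G>T:A"`, the signature of deamination-mediated
#' decay of methylcytosine.
#'
#' @param tetramer 4-base string: the non-CCGG allele (the variant
#'   allele of a lost site, or the reference context of a gained one).
#' @param kind `"lost"` or `"gained"` (annotation only; the class
#'   string is the same either way).
#' @return substitution class string, e.g. `"C:G>T:A"`.
#' @export
classifySubstitution <- function(tetramer, kind = c("lost", "gained")) {
  kind <- match.arg(kind)
  if (nchar(tetramer) != 4L)
    stop("tetramer must have 4 bases", call. = FALSE)
  ref <- c("C", "C", "G", "G")
  obs <- strsplit(toupper(tetramer), "")[[1]]
  d <- which(obs != ref)
  if (length(d) != 1L)
    stop(sprintf("tetramer %s differs from CCGG at %d positions; expected 1",
                 tetramer, length(d)), call. = FALSE)
  b <- obs[d]
  if (d <= 2L) sprintf("C:G>%s:%s", b, .COMP[[b]])
  else sprintf("C:G>%s:%s", .COMP[[b]], b)
}

#' Read a known-variant catalog from VCF
#'
#' @param path VCF path.
#' @return GRanges with `id`, `ref`, `alt` metadata columns (first
#'   alternate allele; SNVs only retain single-base alleles).
#' @export
readVariants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(as.list(gr$ALT), function(a)
    if (length(a)) as.character(a[[1]]) else NA_character_, character(1))
  out <- GRanges(seqnames(gr), IRanges::IRanges(start(gr), end(gr)),
                 id = names(gr), ref = as.character(gr$REF), alt = alt)
  names(out) <- NULL
  out
}

#' Detect lost CCGG sites
#'
#' An annotated site with exactly zero MspI weight across the merged
#' lanes is a lost-site candidate: any read would disprove homozygous
#' loss. When a variant catalog is supplied, candidates overlapping a
#' known variant within the tetramer are flagged, and a
#' variant-filtered list is emitted alongside the unfiltered one; a
#' single-base alternate allele also yields the substitution class.
#'
#' @param counts merged MspI [SiteCounts-class] object.
#' @param variants optional GRanges of known variants (see
#'   [readVariants()]) or a VCF path.
#' @return list with `candidates` (all zero-evidence sites) and
#'   `variant_filtered` (the subset overlapping a known variant).
#'   Columns: chrom, pos, site_id, kind, mspi_evidence, ref_tetramer,
#'   variant_match, substitution_class.
#' @export
detectLostSites <- function(counts, variants = NULL) {
  stopifnot(methods::is(counts, "SiteCounts"))
  if (is.character(variants)) variants <- readVariants(variants)
  zero <- counts@counts == 0
  cand_gr <- counts@sites[zero]
  nc <- length(cand_gr)
  out <- data.frame(
    chrom = as.character(seqnames(cand_gr)),
    pos = start(cand_gr) - 1L,
    site_id = cand_gr$site_id,
    kind = rep("lost", nc),
    mspi_evidence = rep(0, nc),
    ref_tetramer = rep("CCGG", nc),
    variant_match = rep(NA_character_, nc),
    substitution_class = rep(NA_character_, nc),
    stringsAsFactors = FALSE)
  if (!is.null(variants) && length(variants) && nrow(out)) {
    ov <- GenomicRanges::findOverlaps(cand_gr, variants)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- !duplicated(qh)
    qh <- qh[keep]; sh <- sh[keep]
    out$variant_match[qh] <- if (!is.null(variants$id))
      variants$id[sh] else as.character(sh)
    if (!is.null(variants$alt) && !is.null(variants$ref)) {
      off <- start(variants)[sh] - start(cand_gr)[qh] + 1L
      alt <- variants$alt[sh]
      ok <- !is.na(alt) & nchar(alt) == 1L & off >= 1L & off <= 4L
      tet <- vapply(which(ok), function(k) {
        t <- c("C", "C", "G", "G")
        t[off[k]] <- alt[k]
        paste(t, collapse = "")
      }, character(1))
      cls <- vapply(tet, function(t)
        tryCatch(classifySubstitution(t, "lost"),
                 error = function(e) NA_character_), character(1))
      out$substitution_class[qh[ok]] <- unname(cls)
    }
  }
  list(candidates = out,
       variant_filtered = out[!is.na(out$variant_match), , drop = FALSE])
}

#' Detect gained CCGG sites
#'
#' Clusters unassigned alignments by their implied cut coordinate
#' (positions within `slack` bp join one cluster). A cluster whose
#' total fractional weight reaches `min_reads` and whose reference
#' context differs from CCGG by exactly one base becomes a gained-site
#' candidate; the candidate position is the supported position whose
#' tetramer is a 1-substitution neighbor of CCGG (highest implied-
#' position weight, then lowest coordinate). Annotated sites are never
#' reported as gained.
#'
#' @param unassigned data.frame of unassigned alignments (the
#'   `unassigned` slot of a [SiteCounts-class] object, which may be
#'   passed directly).
#' @param genome genome as accepted by [findCCGGSites()].
#' @param sites GRanges of annotated sites.
#' @param min_reads minimum total cluster weight (default 4, the
#'   genome-wide average MspI reads per annotated site).
#' @param slack clustering distance, bp.
#' @return list with `candidates` (chrom, pos, kind, mspi_evidence,
#'   ref_tetramer, substitution_class) and `rejected` (clusters that
#'   failed, with a reason).
#' @export
detectGainedSites <- function(unassigned, genome, sites, min_reads = 4,
                              slack = 2L) {
  if (min_reads < 1) stop("min_reads must be >= 1", call. = FALSE)
  if (methods::is(unassigned, "SiteCounts")) unassigned <- unassigned@unassigned
  genome <- .as_genome(genome)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      kind = character(0), mspi_evidence = numeric(0),
                      ref_tetramer = character(0),
                      substitution_class = character(0),
                      stringsAsFactors = FALSE)
  rejected <- data.frame(chrom = character(0), pos = integer(0),
                         weight = numeric(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (is.null(unassigned) || nrow(unassigned) == 0L)
    return(list(candidates = empty, rejected = rejected))

  site_key <- paste(as.character(seqnames(sites)), start(sites) - 1L)
  cands <- empty
  for (ch in unique(unassigned$chrom)) {
    u <- unassigned[unassigned$chrom == ch, , drop = FALSE]
    w_by_pos <- rowsum(u$weight, group = u$implied_pos)
    pos <- as.integer(rownames(w_by_pos))
    w <- w_by_pos[, 1]
    ord <- order(pos)
    pos <- pos[ord]; w <- w[ord]
    cl <- cumsum(c(1L, as.integer(diff(pos) > slack)))
    chromstr <- as.character(genome[[match(ch, names(genome))]])
    for (g in split(seq_along(pos), cl)) {
      total <- sum(w[g])
      span <- range(pos[g])
      if (total < min_reads) {
        rejected <- rbind(rejected, data.frame(
          chrom = ch, pos = span[1], weight = total,
          reason = "below_min_reads"))
        next
      }
      probe <- seq(span[1] - slack, span[2] + slack)
      probe <- probe[probe >= 0L & probe + 4L <= nchar(chromstr)]
      probe <- probe[!paste(ch, probe) %in% site_key]
      tets <- substring(chromstr, probe + 1L, probe + 4L)
      ndiff <- vapply(tets, function(t)
        sum(strsplit(t, "")[[1]] != c("C", "C", "G", "G")), integer(1))
      hit <- probe[ndiff == 1L]
      if (!length(hit)) {
        rejected <- rbind(rejected, data.frame(
          chrom = ch, pos = span[1], weight = total,
          reason = "no_single_substitution_tetramer"))
        next
      }
      support <- vapply(hit, function(p) {
        i <- match(p, pos[g])
        if (is.na(i)) 0 else w[g][i]
      }, numeric(1))
      best <- hit[order(-support, hit)][1]
      tet <- substring(chromstr, best + 1L, best + 4L)
      cands <- rbind(cands, data.frame(
        chrom = ch, pos = best, kind = "gained", mspi_evidence = total,
        ref_tetramer = tet,
        substitution_class = classifySubstitution(tet, "gained"),
        stringsAsFactors = FALSE))
    }
  }
  rownames(cands) <- NULL
  list(candidates = cands, rejected = rejected)
}
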