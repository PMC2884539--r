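# Genomic-compartment summaries: promoter / gene body / intergenic
# labels, repeat overlap, and TSS-distance angle-category profiles.

#' Annotate CCGG sites by genomic compartment
#'
#' Each site receives exactly one label: `promoter` when its signed
#' strand-oriented distance to the nearest transcription start site is
#' within `promoter_bp` (default +/- 2 kb), otherwise `gene_body` when
#' it lies inside a gene span, otherwise `intergenic`. Negative
#' distances are upstream of the TSS. Overlapping genes are resolved
#' by nearest TSS; promoter outranks gene body.
#'
#' @param sites GRanges of CCGG sites with site_id.
#' @param genes GRanges of gene spans with strand (`+`/`-`); a
#'   strandless record is an error. The TSS is the start of the span
#'   on `+`, the end on `-`.
#' @param repeats optional GRanges of repeat elements; a `family` (or
#'   `name`) metadata column is passed through as `repeat_class`.
#' @param promoter_bp promoter half-width around the TSS, bp.
#' @return data.frame: site_id, compartment, repeat_class (NA when not
#'   in a repeat), tss_distance.
#' @export
annotateSites <- function(sites, genes, repeats = NULL, promoter_bp = 2000L) {
  if (length(genes) == 0L)
    stop("genes must contain at least one record", call. = FALSE)
  str <- as.character(strand(genes))
  if (any(str == "*"))
    stop("gene records must be stranded (+/-)", call. = FALSE)
  tss_pos <- ifelse(str == "+", start(genes), end(genes))
  tss <- GRanges(seqnames(genes), IRanges::IRanges(tss_pos, width = 1L))
  site_pt <- GRanges(seqnames(sites), IRanges::IRanges(start(sites), width = 1L))
  near <- GenomicRanges::nearest(site_pt, tss, ignore.strand = TRUE)
  if (any(is.na(near)))
    stop("some sites lie on chromosomes without any gene", call. = FALSE)
  d_raw <- start(site_pt) - tss_pos[near]
  tss_distance <- ifelse(str[near] == "+", d_raw, -d_raw)

  in_gene <- GenomicRanges::countOverlaps(site_pt, genes,
                                          ignore.strand = TRUE) > 0
  compartment <- ifelse(abs(tss_distance) <= promoter_bp, "promoter",
                        ifelse(in_gene, "gene_body", "intergenic"))

  repeat_class <- rep(NA_character_, length(sites))
  if (!is.null(repeats) && length(repeats)) {
    ov <- GenomicRanges::findOverlaps(site_pt, repeats, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- !duplicated(qh)
    fam <- if (!is.null(repeats$family)) repeats$family
           else if (!is.null(repeats$name)) repeats$name
           else rep("repeat", length(repeats))
    repeat_class[qh[keep]] <- fam[sh[keep]]
  }
  data.frame(site_id = sites$site_id, compartment = compartment,
             repeat_class = repeat_class, tss_distance = tss_distance,
             stringsAsFactors = FALSE)
}

#' Angle distributions per genomic compartment
#'
#' @param angles an [AngleRecords-class] object.
#' @param annotations data.frame from [annotateSites()].
#' @param by group by `"compartment"` or by `"repeat"` (repeat vs
#'   unique sequence).
#' @return list with `summary` (group, n, median_angle) and `values`
#'   (named list of angle vectors). Empty groups are omitted with a
#'   warning.
#' @export
compartmentDensity <- function(angles, annotations,
                               by = c("compartment", "repeat")) {
  by <- match.arg(by)
  stopifnot(methods::is(angles, "AngleRecords"))
  ann <- annotations[match(angles@sites$site_id, annotations$site_id), ]
  grp <- if (by == "compartment") ann$compartment
         else ifelse(is.na(ann$repeat_class), "unique", "repeat")
  sc <- angles@status == "scored"
  values <- split(angles@angle[sc], grp[sc])
  empty <- vapply(values, length, integer(1)) == 0L
  if (any(empty)) {
    warning("empty groups omitted: ", paste(names(values)[empty],
                                            collapse = ", "))
    values <- values[!empty]
  }
  summary <- data.frame(group = names(values),
                        n = vapply(values, length, integer(1)),
                        median_angle = vapply(values, stats::median,
                                              numeric(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, values = values)
}

#' Angle-category profile by distance from the TSS
#'
#' Sites are grouped into three angle classes, [0,30], (30,60] and
#' (60,90] degrees (fully methylated to fully unmethylated), and
#' tabulated in distance bins from the nearest TSS. Counts and
#' per-bin percentages are returned; percentages of a non-empty bin
#' sum to 100.
#'
#' @param angles an [AngleRecords-class] object.
#' @param annotations data.frame from [annotateSites()].
#' @param bin_bp distance bin width, bp.
#' @param max_dist half-range of the profile, bp.
#' @param repeat_only restrict to sites inside repeat elements.
#' @return list: `counts` and `percent` (matrices, bins x classes),
#'   `bin_mid` (bin midpoints), `n_in_range` (scored sites profiled).
#' @export
tssProfile <- function(angles, annotations, bin_bp = 1000L,
                       max_dist = 20000L, repeat_only = FALSE) {
  if (bin_bp <= 0) stop("bin_bp must be positive", call. = FALSE)
  stopifnot(methods::is(angles, "AngleRecords"))
  ann <- annotations[match(angles@sites$site_id, annotations$site_id), ]
  sel <- angles@status == "scored" & abs(ann$tss_distance) <= max_dist
  if (repeat_only) sel <- sel & !is.na(ann$repeat_class)
  d <- ann$tss_distance[sel]
  a <- angles@angle[sel]
  edges <- seq(-max_dist, max_dist, by = bin_bp)
  dist_bin <- cut(d, breaks = edges, include.lowest = TRUE)
  cls <- cut(a, breaks = c(0, 30, 60, 90), include.lowest = TRUE,
             labels = c("0-30", "31-60", "61-90"))
  counts <- unclass(table(dist_bin, cls))
  rs <- rowSums(counts)
  percent <- 100 * sweep(counts, 1, pmax(rs, 1), "/")
  percent[rs == 0, ] <- NA_real_
  list(counts = counts, percent = percent,
       bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
       n_in_range = sum(sel))
}
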