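#' SiteCounts: fractional tag counts per CCGG site
#'
#' Holds the per-site fractional read counts of one enzyme library
#' (HpaII or MspI) over a fixed universe of annotated CCGG sites,
#' together with the bookkeeping needed for conservation checks and
#' downstream polymorphic-site discovery: per-alignment assignment
#' records, unassigned alignments, and the tally of reads dropped at
#' alignment (no hit, too many hits, or too many ambiguous bases).
#'
#' Fractional counting: a read whose tag aligns to n genomic locations
#' contributes 1/n at each location, so repetitive tags are spread
#' rather than discarded (up to the retention cap of 10 locations).
#'
#' @slot sites a [GenomicRanges::GRanges] of CCGG sites with a
#'   `site_id` metadata column; one range per site, width 4.
#' @slot counts numeric vector, fractional read count per site.
#' @slot enzyme `"HpaII"` or `"MspI"`.
#' @slot nRetained number of reads that survived QC and alignment
#'   retention and therefore carry weight in `counts` + `unassigned`.
#' @slot dropped data.frame with columns `reason` and `reads`: reads
#'   removed before assignment (no alignment, > 10 locations, N filter).
#' @slot assignments data.frame of per-alignment assignments
#'   (chrom, start, strand, weight, site_id, flank).
#' @slot unassigned data.frame of alignments not adjacent to any
#'   annotated site (input to [detectGainedSites()]).
#'
#' @seealso [assignToSites()], [fixedCounts()], [mergeLanes()]
#' @export
setClass("SiteCounts",
  representation(
    sites = "GRanges",
    counts = "numeric",
    enzyme = "character",
    nRetained = "numeric",
    dropped = "data.frame",
    assignments = "data.frame",
    unassigned = "data.frame"
  )
)

setValidity("SiteCounts", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@sites))
    msg <- c(msg, "length(counts) must equal length(sites)")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@enzyme) != 1L ||
      !object@enzyme %in% c("HpaII", "MspI"))
    msg <- c(msg, "enzyme must be \"HpaII\" or \"MspI\"")
  if (is.null(object@sites$site_id))
    msg <- c(msg, "sites must carry a site_id metadata column")
  if (length(msg)) msg else TRUE
})

#' AngleRecords: angle-normalized methylation scores per site
#'
#' The result of normalizing a HpaII library by an MspI reference via
#' the angle transformation. For each site with per-million fixed
#' counts (h, m), the methylation score is the angle
#' B = atan2(h, m) in degrees: 0 means fully methylated (no HpaII
#' signal), 90 fully unmethylated. The confidence distance
#' c = sqrt(h^2 + m^2) grows with read depth, so equal angles can be
#' ranked by how much evidence supports them. Sites with neither HpaII
#' nor MspI signal were not assayed and are flagged `no_data` (angle
#' NA) rather than scored 0.
#'
#' @slot sites GRanges of the scored CCGG sites (site_id in mcols).
#' @slot angle numeric, degrees in [0, 90]; NA iff status is no_data.
#' @slot cDist numeric, Euclidean norm of (MspI, HpaII) per-million
#'   fixed counts.
#' @slot status character, `"scored"` or `"no_data"` per site.
#' @seealso [scoreSample()], [computeAngle()], [exportTracks()]
#' @export
setClass("AngleRecords",
  representation(
    sites = "GRanges",
    angle = "numeric",
    cDist = "numeric",
    status = "character"
  )
)

setValidity("AngleRecords", function(object) {
  n <- length(object@sites)
  msg <- character()
  if (length(object@angle) != n || length(object@cDist) != n ||
      length(object@status) != n)
    msg <- c(msg, "angle, cDist and status must match length(sites)")
  if (!all(object@status %in% c("scored", "no_data")))
    msg <- c(msg, "status values must be 'scored' or 'no_data'")
  sc <- object@status == "scored"
  if (any(is.na(object@angle[sc])))
    msg <- c(msg, "scored records must have a non-NA angle")
  ang <- object@angle[sc]
  if (length(ang) && (any(ang < 0) || any(ang > 90)))
    msg <- c(msg, "angles must lie in [0, 90] degrees")
  if (any(!is.na(object@angle[!sc])))
    msg <- c(msg, "no_data records must have NA angle")
  if (any(object@cDist < 0))
    msg <- c(msg, "cDist must be non-negative")
  if (length(msg)) msg else TRUE
})
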