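#' Site ranges of a result object
#' @param x a SiteCounts or AngleRecords object.
#' @return the GRanges of CCGG sites the object is defined over.
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' Fractional tag counts per site
#' @param x a SiteCounts object.
#' @return numeric vector of fractional counts, one per site.
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' Fixed (total-normalized) counts per site
#'
#' A site's fixed count is its fractional count divided by the total
#' fractional count over all sites in the same sample; fixed counts sum
#' to 1 and make libraries of different depth comparable.
#'
#' @param x a SiteCounts object.
#' @return numeric vector summing to 1.
#' @export
setGeneric("fixedCounts", function(x) standardGeneric("fixedCounts"))

#' Enzyme of a count table
#' @param x a SiteCounts object.
#' @return `"HpaII"` or `"MspI"`.
#' @export
setGeneric("enzymeName", function(x) standardGeneric("enzymeName"))

#' Angle scores in degrees
#' @param x an AngleRecords object.
#' @return numeric vector in [0, 90]; NA for no_data sites.
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' Confidence distances
#' @param x an AngleRecords object.
#' @return numeric vector of Euclidean norms on the per-million scale.
#' @export
setGeneric("cDist", function(x) standardGeneric("cDist"))

#' Scoring status per site
#' @param x an AngleRecords object.
#' @return character vector, `"scored"` or `"no_data"`.
#' @export
setGeneric("scoreStatus", function(x) standardGeneric("scoreStatus"))

#' @describeIn siteRanges sites of a count table
#' @export
setMethod("siteRanges", "SiteCounts", function(x) x@sites)

#' @describeIn siteRanges sites of an angle record set
#' @export
setMethod("siteRanges", "AngleRecords", function(x) x@sites)

#' @describeIn tagCounts fractional counts
#' @export
setMethod("tagCounts", "SiteCounts", function(x) x@counts)

#' @describeIn fixedCounts fixed counts of one sample
#' @export
setMethod("fixedCounts", "SiteCounts", function(x) {
  tot <- sum(x@counts)
  if (tot == 0)
    stop("all-zero sample: fixed counts are undefined", call. = FALSE)
  x@counts / tot
})

#' @describeIn enzymeName enzyme label
#' @export
setMethod("enzymeName", "SiteCounts", function(x) x@enzyme)

#' @describeIn angles angle per site
#' @export
setMethod("angles", "AngleRecords", function(x) x@angle)

#' @describeIn cDist confidence distance per site
#' @export
setMethod("cDist", "AngleRecords", function(x) x@cDist)

#' @describeIn scoreStatus status per site
#' @export
setMethod("scoreStatus", "AngleRecords", function(x) x@status)

setMethod("show", "SiteCounts", function(object) {
  n <- length(object@sites)
  cov <- if (n) mean(object@counts > 0) else NA_real_
  cat(sprintf("SiteCounts (%s): %d sites, %.1f fractional reads assigned\n",
              object@enzyme, n, sum(object@counts)))
  if (n)
    cat(sprintf("  coverage: %s of sites with >= 1 read; mean %.2f reads/site\n",
                .pct(cov), mean(object@counts)))
  if (nrow(object@dropped))
    cat(sprintf("  dropped reads: %s\n",
                paste(sprintf("%s=%g", object@dropped$reason,
                              object@dropped$reads), collapse = ", ")))
  invisible(object)
})

setMethod("show", "AngleRecords", function(object) {
  n <- length(object@sites)
  sc <- object@status == "scored"
  cat(sprintf("AngleRecords: %d sites (%d scored, %d no_data)\n",
              n, sum(sc), sum(!sc)))
  if (any(sc))
    cat(sprintf("  angle: median %.1f deg, IQR [%.1f, %.1f]\n",
                stats::median(object@angle[sc]),
                stats::quantile(object@angle[sc], 0.25),
                stats::quantile(object@angle[sc], 0.75)))
  invisible(object)
})

#' Convert results to a data.frame
#'
#' @param x a SiteCounts or AngleRecords object.
#' @param row.names,optional ignored (S3 compatibility).
#' @param ... ignored.
#' @return a data.frame keyed by site_id with chrom/pos columns.
#' @exportS3Method base::as.data.frame
as.data.frame.SiteCounts <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    site_id = x@sites$site_id,
    chrom = as.character(seqnames(x@sites)),
    pos = start(x@sites) - 1L,
    count = x@counts,
    fixed = if (sum(x@counts) > 0) x@counts / sum(x@counts) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @rdname as.data.frame.SiteCounts
#' @exportS3Method base::as.data.frame
as.data.frame.AngleRecords <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    site_id = x@sites$site_id,
    chrom = as.character(seqnames(x@sites)),
    pos = start(x@sites) - 1L,
    angle_deg = x@angle,
    c_dist = x@cDist,
    status = x@status,
    stringsAsFactors = FALSE
  )
}

setMethod("as.data.frame", "SiteCounts",
          function(x, row.names = NULL, optional = FALSE, ...)
            as.data.frame.SiteCounts(x))
setMethod("as.data.frame", "AngleRecords",
          function(x, row.names = NULL, optional = FALSE, ...)
            as.data.frame.AngleRecords(x))
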