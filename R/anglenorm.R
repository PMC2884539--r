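#' Angle transformation of paired HpaII/MspI signal
#'
#' For per-million fixed counts h (HpaII) and m (MspI) at one site,
#' the methylation score is the angle B = atan2(h, m) in degrees:
#' h = 0 gives 0 (fully methylated), m = 0 with h > 0 gives 90 (fully
#' unmethylated), h = m gives 45. The confidence distance is
#' c = sqrt(h^2 + m^2). B is invariant to scaling both inputs by a
#' common factor, which is what cancels site-level capture-efficiency
#' variation shared by the two libraries. Both inputs 0 means the site
#' was not assayed: status `no_data`, angle NA.
#'
#' @param hpaii_fixed,mspi_fixed non-negative per-million fixed
#'   counts (vectors of equal length).
#' @return data.frame with columns angle_deg, c_dist, status.
#' @examples
#' computeAngle(c(0, 3, 2), c(5, 0, 2))
#' @export
computeAngle <- function(hpaii_fixed, mspi_fixed) {
  if (length(hpaii_fixed) != length(mspi_fixed))
    stop("input vectors must have equal length", call. = FALSE)
  if (any(hpaii_fixed < 0) || any(mspi_fixed < 0))
    stop("counts must be non-negative", call. = FALSE)
  no_data <- hpaii_fixed == 0 & mspi_fixed == 0
  angle <- ifelse(no_data, NA_real_,
                  atan2(hpaii_fixed, mspi_fixed) * 180 / pi)
  data.frame(angle_deg = angle,
             c_dist = sqrt(hpaii_fixed^2 + mspi_fixed^2),
             status = ifelse(no_data, "no_data", "scored"),
             stringsAsFactors = FALSE)
}

#' Score a HpaII sample against an MspI reference
#'
#' Normalizes the HpaII library by the MspI library through the angle
#' transformation, on the fixed (total-normalized) counts scaled to
#' per-million. The two tables must share the site universe; an MspI
#' table may be reused as a common reference across many HpaII
#' samples. Sites with no signal in either library are flagged
#' `no_data`, not dropped. A table whose total count is zero
#' contributes zero fixed counts everywhere (such a degenerate sample
#' cannot be total-normalized).
#'
#' @param hpaii,mspi [SiteCounts-class] objects over the same sites.
#' @return an [AngleRecords-class] object.
#' @export
scoreSample <- function(hpaii, mspi) {
  stopifnot(methods::is(hpaii, "SiteCounts"), methods::is(mspi, "SiteCounts"))
  .check_same_universe(hpaii, mspi)
  fixed_or_zero <- function(x) {
    tot <- sum(x@counts)
    if (tot > 0) x@counts / tot else rep(0, length(x@counts))
  }
  h <- fixed_or_zero(hpaii) * 1e6
  m <- fixed_or_zero(mspi) * 1e6
  rec <- computeAngle(h, m)
  methods::new("AngleRecords", sites = hpaii@sites, angle = rec$angle_deg,
               cDist = rec$c_dist, status = rec$status)
}

#' Correlate angle scores with reference methylation values
#'
#' Ordinary least-squares fit of the reference methylation values on
#' the angle, as used to validate the angle score against an
#' independent quantitative assay on a subset of sites.
#'
#' @param angle numeric angle values (or an [AngleRecords-class]
#'   object, in which case `site_id` of `reference` selects sites).
#' @param reference numeric reference methylation values paired with
#'   `angle`.
#' @return list with `r_squared`, `pearson_r`, `n`.
#' @export
correlateWithReference <- function(angle, reference) {
  if (methods::is(angle, "AngleRecords")) angle <- angles(angle)
  ok <- !is.na(angle) & !is.na(reference)
  angle <- angle[ok]; reference <- reference[ok]
  if (length(angle) < 3L)
    stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(reference) == 0)
    stop("reference values are constant; correlation undefined",
         call. = FALSE)
  if (stats::sd(angle) == 0)
    stop("angle values are constant; correlation undefined", call. = FALSE)
  r <- stats::cor(angle, reference)
  list(r_squared = r^2, pearson_r = r, n = length(angle))
}

#' Export angle records as genome-browser tracks
#'
#' Writes a variableStep wiggle of angle values (1-based positions at
#' site pos + 1) and a BED file of untested (`no_data`) loci. Scored
#' sites with angle exactly 0 are written as the sentinel -1.0 so that
#' tested-but-fully-methylated loci remain visible in a browser.
#'
#' @param x an [AngleRecords-class] object.
#' @param wig_path output wiggle path.
#' @param bed_path output BED path for no_data loci (optional).
#' @param track_name track name written in the wiggle header.
#' @return invisibly, `wig_path`.
#' @export
exportTracks <- function(x, wig_path, bed_path = NULL,
                         track_name = "helptag_angle") {
  stopifnot(methods::is(x, "AngleRecords"))
  con <- file(wig_path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=%s", track_name), con)
  sc <- x@status == "scored"
  chroms <- as.character(seqnames(x@sites))
  for (ch in unique(chroms[sc])) {
    sel <- sc & chroms == ch
    writeLines(sprintf("variableStep chrom=%s", ch), con)
    val <- ifelse(x@angle[sel] == 0, -1.0, x@angle[sel])
    writeLines(sprintf("%d %g", start(x@sites)[sel], round(val, 4)), con)
  }
  if (!is.null(bed_path)) {
    nd <- x@sites[!sc]
    exportBED(nd, bed_path)
  }
  invisible(wig_path)
}

#' Write angle records as TSV
#' @param x an [AngleRecords-class] object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAngles <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
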