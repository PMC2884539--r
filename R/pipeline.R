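#' Pipeline configuration
#'
#' Collects paths and thresholds for [runPipeline()]. Threshold
#' defaults are the assay's canonical values: up to 2 mismatches per
#' alignment, up to 10 alignment locations per tag, 4 reads to call a
#' gained site, and a +/- 2 kb promoter window.
#'
#' @param genome FASTA path or DNAStringSet.
#' @param hpaii FASTQ path(s) for the HpaII library (several lanes are
#'   merged).
#' @param mspi FASTQ path(s) for the MspI library, or the path of a
#'   counts TSV written by [writeCounts()] to reuse a common MspI
#'   reference dataset.
#' @param genes optional BED of gene spans with strand.
#' @param repeats optional BED of repeat elements (family in the name
#'   field).
#' @param variants optional VCF of known variants.
#' @param out_dir output directory (created if needed).
#' @param prefix output file prefix.
#' @param max_mismatch,max_hits,min_gained,promoter_bp,slack
#'   thresholds (see module functions).
#' @param seed integer seed recorded in the provenance file.
#' @return list of class `HelpTagPipelineConfig`.
#' @export
helptagConfig <- function(genome, hpaii = NULL, mspi = NULL, genes = NULL,
                          repeats = NULL, variants = NULL,
                          out_dir = ".", prefix = "sample",
                          max_mismatch = 2L, max_hits = 10L,
                          min_gained = 4, promoter_bp = 2000L,
                          slack = 2L, seed = 1L) {
  cfg <- list(genome = genome, hpaii = hpaii, mspi = mspi, genes = genes,
              repeats = repeats, variants = variants, out_dir = out_dir,
              prefix = prefix, max_mismatch = as.integer(max_mismatch),
              max_hits = as.integer(max_hits), min_gained = min_gained,
              promoter_bp = as.integer(promoter_bp),
              slack = as.integer(slack), seed = as.integer(seed))
  class(cfg) <- "HelpTagPipelineConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.count_lanes <- function(paths, genome, sites, enzyme, cfg, out, tag) {
  lanes <- lapply(seq_along(paths), function(i) {
    reads <- .stage(paste0("qc_", tag), {
      r <- readFastq(paths[i])
      rep <- qcReport(r)
      writeQCReport(rep, file.path(cfg$out_dir,
        sprintf("%s_%s_lane%d_qc.tsv", cfg$prefix, tag, i)))
      r
    })
    .stage(paste0("count_", tag),
           countLibrary(reads, genome, sites, enzyme,
                        max_mismatch = cfg$max_mismatch,
                        max_hits = cfg$max_hits, slack = cfg$slack))
  })
  if (length(lanes) > 1L) mergeLanes(lanes) else lanes[[1]]
}

#' Run the full analysis workflow
#'
#' Executes QC, alignment, fractional counting (merging lanes),
#' angle normalization, bias diagnostics, polymorphic-site discovery,
#' compartment summaries when annotations are supplied, and track
#' export. Output is a deterministic function of the inputs and the
#' configuration; a provenance YAML recording versions, seed and
#' parameters is written alongside the results.
#'
#' @param cfg a [helptagConfig()] object.
#' @return invisibly, a list with the main result objects
#'   (`hpaii`, `mspi`, `angles`, `bias_gc`, `bias_len`, `lost`,
#'   `gained`, `compartments`, `files`).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "HelpTagPipelineConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pfx <- function(s) file.path(cfg$out_dir, paste0(cfg$prefix, "_", s))

  genome <- .stage("refgenome", .as_genome(cfg$genome))
  sites <- .stage("refgenome", findCCGGSites(genome))
  frags <- .stage("refgenome", virtualDigest(sites))
  gcw <- .stage("refgenome", gcWindows(genome, sites))

  mspi <- if (length(cfg$mspi) == 1L &&
              is.character(cfg$mspi) && grepl("\\.tsv$", cfg$mspi)) {
    .stage("count_mspi", readCounts(cfg$mspi, "MspI"))
  } else if (!is.null(cfg$mspi)) {
    .count_lanes(cfg$mspi, genome, sites, "MspI", cfg, pfx, "mspi")
  } else stop("pipeline requires an MspI dataset (reads or reference table)",
              call. = FALSE)
  hpaii <- if (!is.null(cfg$hpaii))
    .count_lanes(cfg$hpaii, genome, sites, "HpaII", cfg, pfx, "hpaii")
  else NULL

  files <- character(0)
  writeCounts(mspi, f <- pfx("mspi_counts.tsv")); files <- c(files, f)
  angles <- NULL
  if (!is.null(hpaii)) {
    writeCounts(hpaii, f <- pfx("hpaii_counts.tsv")); files <- c(files, f)
    angles <- .stage("angle", scoreSample(hpaii, mspi))
    writeAngles(angles, f <- pfx("angles.tsv")); files <- c(files, f)
    .stage("tracks", exportTracks(angles, pfx("angles.wig"),
                                  pfx("untested.bed")))
    files <- c(files, pfx("angles.wig"), pfx("untested.bed"))
  }

  bias_gc <- .stage("bias", gcRepresentation(mspi, gcw))
  bias_len <- .stage("bias", fragmentRepresentation(mspi, frags))
  utils::write.table(bias_gc, f <- pfx("bias_gc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  utils::write.table(bias_len, f <- pfx("bias_fragment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  variants <- if (is.character(cfg$variants))
    .stage("polymorphic", readVariants(cfg$variants)) else cfg$variants
  lost <- .stage("polymorphic", detectLostSites(mspi, variants))
  gained <- .stage("polymorphic",
                   detectGainedSites(mspi, genome, sites,
                                     min_reads = cfg$min_gained,
                                     slack = cfg$slack))
  utils::write.table(lost$candidates, f <- pfx("lost_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  utils::write.table(gained$candidates, f <- pfx("gained_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  compartments <- NULL
  if (!is.null(cfg$genes) && !is.null(angles)) {
    genes <- if (is.character(cfg$genes))
      rtracklayer::import(cfg$genes) else cfg$genes
    repeats <- if (is.character(cfg$repeats))
      rtracklayer::import(cfg$repeats) else cfg$repeats
    ann <- .stage("compartments",
                  annotateSites(sites, genes, repeats,
                                promoter_bp = cfg$promoter_bp))
    dens <- .stage("compartments", compartmentDensity(angles, ann))
    prof <- .stage("compartments", tssProfile(angles, ann))
    utils::write.table(ann, f <- pfx("site_annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    utils::write.table(dens$summary, f <- pfx("compartment_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    compartments <- list(annotation = ann, density = dens, profile = prof)
  }

  prov <- list(
    package = "helptag",
    version = as.character(utils::packageVersion("helptag")),
    r_version = R.version.string,
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = cfg$seed,
    parameters = cfg[c("max_mismatch", "max_hits", "min_gained",
                       "promoter_bp", "slack", "prefix")],
    inputs = Filter(Negate(is.null),
                    lapply(cfg[c("genome", "hpaii", "mspi", "genes",
                                 "repeats", "variants")],
                           function(x) if (is.character(x)) x else class(x))))
  yaml::write_yaml(prov, pfx("provenance.yaml"))

  invisible(list(hpaii = hpaii, mspi = mspi, angles = angles,
                 bias_gc = bias_gc, bias_len = bias_len,
                 lost = lost, gained = gained,
                 compartments = compartments,
                 files = c(files, pfx("provenance.yaml"))))
}
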