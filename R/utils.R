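# Shared constants and small helpers.

# 3' anchor expected in every genuine read: CG cohesive end + EcoP15I site.
ANCHOR_MOTIF <- "CGCTGCTG"
ANCHOR_MOTIF_RC <- "CAGCAGCG"
READ_LENGTH <- 36L
TAG_LENGTH <- 27L

# Downstream adapter bases appended after the anchor to pad reads to 36 bp.
ADAPTER_FILLER <- "AGATCGGAAGAGCTCGTATG"

DNA_BASES <- c("A", "C", "G", "T")

.complement_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a character vector of DNA sequences
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @keywords internal
revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}

#' @keywords internal
.check_dna_chars <- function(seq, name = "sequence") {
  bad <- regexpr("[^ACGTNacgtn]", seq)
  if (bad > 0L) {
    stop(sprintf("non-DNA character '%s' at position %d of %s",
                 substr(seq, bad, bad), bad, name), call. = FALSE)
  }
  invisible(TRUE)
}

# Format a fraction as percent for messages.
.pct <- function(x) sprintf("%.1f%%", 100 * x)
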