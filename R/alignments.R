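#' Read one sample's alignments
#'
#' Loads a coordinate-sorted BAM (or plain SAM, converted on the fly) into a
#' \code{GAlignments} object carrying mapping quality and the read sequence,
#' which is all downstream frame/haplotype operations need.
#'
#' @param path BAM or SAM file.
#' @return A \code{GenomicAlignments::GAlignments} with metadata columns
#'   \code{mapq} and \code{seq}.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(what = c("mapq", "seq"))
  GenomicAlignments::readGAlignments(path, param = param)
}

# Accepts a named list/vector of paths or preloaded GAlignments; returns a
# named list of GAlignments. Sample names are taken from names().
as_alignment_list <- function(alignments) {
  if (methods::is(alignments, "GAlignments")) alignments <- list(alignments)
  if (is.null(names(alignments)) || any(names(alignments) == "")) {
    stop("alignments must be named by sample", call. = FALSE)
  }
  lapply(alignments, function(a) {
    if (methods::is(a, "GAlignments")) a else read_alignments(a)
  })
}

# Per-read indel extents in reference space (IRangesList, absolute
# coordinates). Insertions appear as zero-width ranges at the insertion point.
indel_ranges <- function(gal) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(gal), ops = c("I", "D", "N"))
  IRanges::shift(rl, GenomicAlignments::start(gal) - 1L)
}

# Indices of reads that completely span the 0-based half-open frame
# [start0, end0), have mapq >= min_mapq, and carry no indel operation
# overlapping the frame (insertion points strictly inside count as overlap).
spanning_read_idx <- function(gal, contig, start0, end0, min_mapq) {
  mq <- S4Vectors::mcols(gal)$mapq
  keep <- which(as.character(GenomicAlignments::seqnames(gal)) == contig &
                  GenomicAlignments::start(gal) <= start0 + 1L &
                  GenomicAlignments::end(gal) >= end0 &
                  !is.na(mq) & mq >= min_mapq)
  if (!length(keep)) return(integer(0))
  has_indel <- grepl("[IDN]", GenomicAlignments::cigar(gal)[keep])
  if (any(has_indel)) {
    ir <- indel_ranges(gal[keep[has_indel]])
    st <- IRanges::start(ir)
    en <- IRanges::end(ir)
    hit <- vapply(seq_along(ir), function(i) {
      any(st[[i]] <= end0 & pmax(en[[i]], st[[i]]) >= start0 + 1L)
    }, logical(1))
    keep <- c(keep[!has_indel], keep[has_indel][!hit])
  }
  sort(keep)
}

# Read sequences laid out in reference space (soft clips and insertions
# removed, deletions gap-filled), as a character vector parallel to gal.
reference_space_seq <- function(gal) {
  as.character(GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(gal)$seq, GenomicAlignments::cigar(gal)))
}
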