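#' Define fixed-width sliding-frame loci over a reference
#'
#' Tiles each contig with frames of \code{frame_size} bp starting at 0,
#' \code{frame_distance} apart (start-to-start); a trailing partial frame is
#' dropped so every locus has identical width. Coordinates are 0-based
#' half-open, matching BED.
#'
#' @param ref_lengths Named integer vector of contig lengths, or a
#'   \code{DNAStringSet}.
#' @param frame_size Frame width in bp (default 40).
#' @param frame_distance Start-to-start distance between consecutive frames
#'   (default 40, i.e. contiguous non-overlapping frames). Must be >=
#'   \code{frame_size}.
#' @return data.frame with columns \code{contig}, \code{start}, \code{end}
#'   (0-based half-open) and \code{locus_id} (\code{"contig:start-end"}).
#' @examples
#' define_frames(c(chr1 = 120L), frame_size = 40, frame_distance = 40)
#' @export
define_frames <- function(ref_lengths, frame_size = 40L, frame_distance = 40L) {
  if (methods::is(ref_lengths, "DNAStringSet")) {
    ref_lengths <- stats::setNames(Biostrings::width(ref_lengths),
                                   names(ref_lengths))
  }
  if (length(ref_lengths) == 0L || is.null(names(ref_lengths)) ||
      any(names(ref_lengths) == "") || any(is.na(ref_lengths))) {
    stop("ref_lengths must be a named vector of known contig lengths",
         call. = FALSE)
  }
  if (frame_size < 1L) stop("frame_size must be >= 1", call. = FALSE)
  if (frame_distance < frame_size) {
    stop("frame_distance must be >= frame_size", call. = FALSE)
  }
  out <- lapply(names(ref_lengths), function(cg) {
    L <- ref_lengths[[cg]]
    if (L < frame_size) return(NULL)
    starts <- seq.int(0L, L - frame_size, by = frame_distance)
    data.frame(contig = cg, start = starts, end = starts + frame_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(contig = character(), start = integer(), end = integer())
  }
  out$locus_id <- sprintf("%s:%d-%d", out$contig, out$start, out$end)
  out
}

#' Count reads completely spanning a frame
#'
#' A read is counted iff its aligned reference interval contains the whole
#' frame, its mapping quality is at least \code{min_mapq}, and no
#' insertion/deletion operation overlaps the frame (consistent with
#' indel-free haplotyping).
#'
#' @param frame One-row data.frame (or list) with \code{contig},
#'   \code{start}, \code{end} in 0-based half-open coordinates.
#' @param alignments A \code{GAlignments} (with \code{mapq} metadata) or a
#'   BAM/SAM path for one sample.
#' @param min_mapq Minimum mapping quality (default 30).
#' @return Integer spanning-read count.
#' @export
spanning_depth <- function(frame, alignments, min_mapq = 30L) {
  if (min_mapq < 0L) stop("min_mapq must be >= 0", call. = FALSE)
  if (!methods::is(alignments, "GAlignments")) {
    alignments <- read_alignments(alignments)
  }
  length(spanning_read_idx(alignments, frame$contig, frame$start, frame$end,
                           min_mapq))
}

#' Spanning-read depth matrix across frames and samples
#'
#' @param frames Frame data.frame from \code{\link{define_frames}}.
#' @param alignments Named list of per-sample \code{GAlignments} or BAM paths.
#' @param min_mapq Minimum mapping quality (default 30).
#' @return Integer matrix, rows = \code{locus_id}, columns = samples.
#' @export
spanning_depth_matrix <- function(frames, alignments, min_mapq = 30L) {
  aln <- as_alignment_list(alignments)
  frame_gr <- GenomicRanges::GRanges(
    frames$contig, IRanges::IRanges(frames$start + 1L, frames$end))
  depth <- matrix(0L, nrow = nrow(frames), ncol = length(aln),
                  dimnames = list(frames$locus_id, names(aln)))
  for (s in names(aln)) {
    gal <- aln[[s]]
    mq <- S4Vectors::mcols(gal)$mapq
    gal <- gal[!is.na(mq) & mq >= min_mapq]
    hits <- GenomicAlignments::findOverlaps(frame_gr, GenomicRanges::granges(gal),
                                            type = "within")
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    # remove pairs where the read has an indel overlapping that frame
    cig_has <- grepl("[IDN]", GenomicAlignments::cigar(gal)[sh])
    if (any(cig_has)) {
      bad <- vapply(which(cig_has), function(k) {
        ir <- indel_ranges(gal[sh[k]])[[1L]]
        f <- frames[qh[k], ]
        any(IRanges::start(ir) <= f$end &
              pmax(IRanges::end(ir), IRanges::start(ir)) >= f$start + 1L)
      }, logical(1))
      drop <- which(cig_has)[bad]
      if (length(drop)) { qh <- qh[-drop]; sh <- sh[-drop] }
    }
    tab <- tabulate(qh, nbins = nrow(frames))
    depth[, s] <- as.integer(tab)
  }
  depth
}

#' Select loci by spanning-depth completeness across samples
#'
#' Retains a frame iff the fraction of samples whose spanning-read depth is at
#' least \code{min_depth} is strictly greater than \code{completeness}.
#'
#' @param frames Frame data.frame.
#' @param depth Depth matrix from \code{\link{spanning_depth_matrix}} (rows
#'   follow \code{frames}).
#' @param min_depth Minimum spanning reads per sample (default 8).
#' @param completeness Strict lower bound on the fraction of samples passing
#'   (default 0.9).
#' @return The retained subset of \code{frames}.
#' @export
select_loci <- function(frames, depth, min_depth = 8L, completeness = 0.9) {
  if (is.null(dim(depth)) || ncol(depth) == 0L) {
    stop("depth matrix must have at least one sample column", call. = FALSE)
  }
  if (nrow(depth) != nrow(frames)) {
    stop("depth matrix rows must match frames", call. = FALSE)
  }
  frac <- rowMeans(depth >= min_depth)
  frames[frac > completeness, , drop = FALSE]
}
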