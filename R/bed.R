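#' Write / read frame loci as BED
#'
#' BED uses the same 0-based half-open convention as the internal frame
#' table; the locus id is carried in the name column.
#'
#' @param frames Frame data.frame from \code{\link{define_frames}}.
#' @param path BED path.
#' @export
write_frames_bed <- function(frames, path) {
  gr <- GenomicRanges::GRanges(frames$contig,
                               IRanges::IRanges(frames$start + 1L, frames$end))
  names(gr) <- frames$locus_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_frames_bed
#' @export
read_frames_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             locus_id = if (!is.null(gr$name)) gr$name else
               sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}
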