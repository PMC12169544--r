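#' Extract read-backed haplotype counts for one frame and one sample
#'
#' Each read that completely spans the frame, has mapping quality at least
#' \code{min_mapq}, and carries no insertion/deletion overlapping the frame
#' contributes one haplotype string: its base at each SNP position of the
#' locus, in coordinate order (read-backed phasing; mapping orientation is
#' ignored). Reads failing any rule contribute nothing. A frame with zero SNP
#' positions yields the single monomorphic haplotype \code{"."}.
#'
#' @param frame One-row frame (\code{contig}, \code{start}, \code{end};
#'   0-based half-open).
#' @param snp_positions Sorted 1-based positions, all inside the frame.
#' @param alignments One sample's \code{GAlignments} (with \code{mapq} and
#'   \code{seq} metadata) or a BAM/SAM path.
#' @param min_mapq Minimum mapping quality (default 30).
#' @return Named integer vector: haplotype string -> read count.
#' @export
extract_haplotypes <- function(frame, snp_positions, alignments,
                               min_mapq = 30L) {
  if (length(snp_positions) &&
      (any(snp_positions <= frame$start) || any(snp_positions > frame$end))) {
    stop("snp_positions must lie inside the frame ", frame$contig, ":",
         frame$start, "-", frame$end, call. = FALSE)
  }
  if (!methods::is(alignments, "GAlignments")) {
    alignments <- read_alignments(alignments)
  }
  idx <- spanning_read_idx(alignments, frame$contig, frame$start, frame$end,
                           min_mapq)
  if (!length(idx)) return(stats::setNames(integer(0), character(0)))
  if (!length(snp_positions)) {
    return(stats::setNames(length(idx), "."))
  }
  gal <- alignments[idx]
  layered <- reference_space_seq(gal)
  starts <- GenomicAlignments::start(gal)
  haps <- read_haplotype_strings(layered, starts, sort(snp_positions))
  tab <- table(haps)
  stats::setNames(as.integer(tab), names(tab))
}

# bases of each reference-space read string at the given 1-based positions
read_haplotype_strings <- function(layered, starts, snp_positions) {
  cols <- lapply(snp_positions, function(p) {
    off <- p - starts + 1L
    substr(layered, off, off)
  })
  do.call(paste0, cols)
}

#' Haplotype read-count table across loci and samples
#'
#' Applies \code{\link{extract_haplotypes}} to every frame for every sample,
#' reading each sample's alignments once.
#'
#' @param frames Frame data.frame (typically the \code{\link{select_loci}}
#'   output).
#' @param snp_sites data.frame with \code{contig} and 1-based \code{pos}
#'   (e.g. the \code{sites} of a filtered \code{\link{snp_set}}).
#' @param alignments Named list of per-sample \code{GAlignments} or BAM paths.
#' @param min_mapq Minimum mapping quality (default 30).
#' @return Long data.frame: \code{locus_id, sample, haplotype, count}.
#' @export
haplotype_count_table <- function(frames, snp_sites, alignments,
                                  min_mapq = 30L) {
  aln <- as_alignment_list(alignments)
  snps_by_frame <- map_snps_to_frames(frames, snp_sites)
  out <- vector("list", length(aln))
  for (j in seq_along(aln)) {
    out[[j]] <- sample_haplotype_counts(frames, snps_by_frame, aln[[j]],
                                        names(aln)[j], min_mapq)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(locus_id = character(), sample = character(),
                      haplotype = character(), count = integer())
  }
  rownames(res) <- NULL
  res
}

# sorted SNP positions per frame row (list parallel to frames)
map_snps_to_frames <- function(frames, snp_sites) {
  res <- rep(list(integer(0)), nrow(frames))
  if (is.null(snp_sites) || nrow(snp_sites) == 0L || nrow(frames) == 0L) {
    return(res)
  }
  fr <- GenomicRanges::GRanges(frames$contig,
                               IRanges::IRanges(frames$start + 1L, frames$end))
  sn <- GenomicRanges::GRanges(snp_sites$contig,
                               IRanges::IRanges(snp_sites$pos, snp_sites$pos))
  hits <- GenomicRanges::findOverlaps(sn, fr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (i in unique(sh)) {
    res[[i]] <- sort(snp_sites$pos[qh[sh == i]])
  }
  res
}

sample_haplotype_counts <- function(frames, snps_by_frame, gal, sample_name,
                                    min_mapq) {
  mq <- S4Vectors::mcols(gal)$mapq
  gal <- gal[!is.na(mq) & mq >= min_mapq]
  if (!length(gal) || nrow(frames) == 0L) return(NULL)
  fr <- GenomicRanges::GRanges(frames$contig,
                               IRanges::IRanges(frames$start + 1L, frames$end))
  hits <- GenomicAlignments::findOverlaps(fr, GenomicRanges::granges(gal),
                                          type = "within")
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
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
  if (!length(qh)) return(NULL)
  layered <- reference_space_seq(gal)
  starts <- GenomicAlignments::start(gal)
  reads_by_frame <- split(sh, qh)
  out <- vector("list", length(reads_by_frame))
  for (k in seq_along(reads_by_frame)) {
    fi <- as.integer(names(reads_by_frame)[k])
    rs <- reads_by_frame[[k]]
    pos <- snps_by_frame[[fi]]
    if (!length(pos)) {
      out[[k]] <- data.frame(locus_id = frames$locus_id[fi],
                             haplotype = ".", count = length(rs),
                             stringsAsFactors = FALSE)
    } else {
      haps <- read_haplotype_strings(layered[rs], starts[rs], pos)
      tab <- table(haps)
      out[[k]] <- data.frame(locus_id = frames$locus_id[fi],
                             haplotype = names(tab),
                             count = as.integer(tab),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$sample <- sample_name
  res[, c("locus_id", "sample", "haplotype", "count")]
}

#' Discrete dosage call for one (locus, sample) cell
#'
#' With fewer than \code{min_read_count} reads in total the cell is MISSING
#' (returns \code{NULL}). Otherwise each haplotype's percent frequency of the
#' total (including sub-threshold haplotypes; no renormalization) maps to a
#' dosage: below \code{min_freq_pct} or below \code{bounds[1]} it is absent
#' (0); between \code{bounds[2]} and \code{bounds[3]} inclusive it is 1;
#' above \code{bounds[4]} it is 2; inside an open gap between
#' \code{bounds[1]}/\code{bounds[2]} or \code{bounds[3]}/\code{bounds[4]} it
#' is undefined (NA). With the default bounds 15/15/85/85 there is no gap.
#'
#' @param counts Named non-negative integer vector of read counts per
#'   haplotype.
#' @param min_read_count Minimum total reads for a call (default 8).
#' @param min_freq_pct Noise floor in percent (default 10).
#' @param bounds Numeric length-4 non-decreasing frequency interval bounds in
#'   percent (default \code{c(15, 15, 85, 85)}).
#' @param ploidy Ploidy (fixed diploid behaviour; default 2).
#' @return Named integer vector of nonzero (or NA) dosages, or \code{NULL}
#'   for a MISSING cell.
#' @examples
#' call_dosage(c(AC = 10, GT = 10))  # 50/50 -> both dosage 1
#' call_dosage(c(AC = 19, GT = 1))   # 95/5  -> AC dosage 2
#' @export
call_dosage <- function(counts, min_read_count = 8L, min_freq_pct = 10,
                        bounds = c(15, 15, 85, 85), ploidy = 2L) {
  if (any(counts < 0)) stop("negative haplotype counts", call. = FALSE)
  if (length(bounds) != 4L || is.unsorted(bounds) ||
      any(bounds < 0 | bounds > 100)) {
    stop("bounds must be 4 non-decreasing values in [0, 100]", call. = FALSE)
  }
  tot <- sum(counts)
  if (tot < min_read_count) return(NULL)
  freq <- 100 * counts / tot
  d <- dosage_from_freq(freq, min_freq_pct, bounds)
  d[is.na(d) | d > 0L]
}

dosage_from_freq <- function(freq, min_freq_pct, bounds) {
  d <- ifelse(freq < min_freq_pct | freq < bounds[1], 0L,
         ifelse(freq < bounds[2], NA_integer_,
           ifelse(freq <= bounds[3], 1L,
             ifelse(freq <= bounds[4], NA_integer_, 2L))))
  stats::setNames(as.integer(d), names(freq))
}

#' Correctness of a dosage cell
#'
#' TRUE iff the cell is non-missing, all dosages are defined, and they sum to
#' the ploidy (for a diploid: exactly two allele copies called).
#'
#' @param dosage A dosage vector from \code{\link{call_dosage}} (or
#'   \code{NULL} for MISSING).
#' @param ploidy Ploidy (default 2).
#' @return Logical scalar.
#' @export
correctness_flag <- function(dosage, ploidy = 2L) {
  if (is.null(dosage)) return(FALSE)
  if (any(is.na(dosage))) return(FALSE)
  sum(dosage) == ploidy
}

#' Build a dosage matrix from a haplotype count table
#'
#' Applies \code{\link{call_dosage}} to every (locus, sample) cell.
#'
#' @param counts Long count table from \code{\link{haplotype_count_table}}.
#' @param samples Sample universe (defaults to samples present in
#'   \code{counts}).
#' @param loci Locus universe (defaults to loci present in \code{counts}).
#' @inheritParams call_dosage
#' @return A \code{dosage_matrix}: list with \code{calls} (long data.frame
#'   \code{locus_id, sample, haplotype, dosage}; dosage >= 1 or NA),
#'   \code{cells} (one row per non-missing cell: \code{locus_id, sample,
#'   n_reads, dosage_sum}; \code{dosage_sum} is NA when any dosage was
#'   undefined), \code{samples}, \code{loci}, \code{ploidy}. A (locus,
#'   sample) pair absent from \code{cells} is MISSING.
#' @export
dosage_call_table <- function(counts, samples = NULL, loci = NULL,
                              min_read_count = 8L, min_freq_pct = 10,
                              bounds = c(15, 15, 85, 85), ploidy = 2L) {
  if (any(counts$count < 0)) stop("negative haplotype counts", call. = FALSE)
  if (is.null(samples)) samples <- sort(unique(counts$sample))
  if (is.null(loci)) loci <- unique(counts$locus_id)
  key <- paste(counts$locus_id, counts$sample, sep = "\r")
  tot <- stats::ave(counts$count, key, FUN = sum)
  ok <- tot >= min_read_count
  cc <- counts[ok, , drop = FALSE]
  if (nrow(cc)) {
    freq <- 100 * cc$count / tot[ok]
    cc$dosage <- dosage_from_freq(freq, min_freq_pct, bounds)
    keyc <- paste(cc$locus_id, cc$sample, sep = "\r")
    first <- !duplicated(keyc)
    ds <- tapply(cc$dosage, keyc, function(d) sum(d))  # NA if any NA
    nr <- tapply(cc$count, keyc, sum)
    cells <- data.frame(locus_id = cc$locus_id[first],
                        sample = cc$sample[first],
                        stringsAsFactors = FALSE)
    cells$n_reads <- as.integer(nr[paste(cells$locus_id, cells$sample,
                                         sep = "\r")])
    cells$dosage_sum <- as.integer(ds[paste(cells$locus_id, cells$sample,
                                            sep = "\r")])
    calls <- cc[is.na(cc$dosage) | cc$dosage > 0L,
                c("locus_id", "sample", "haplotype", "dosage")]
  } else {
    cells <- data.frame(locus_id = character(), sample = character(),
                        n_reads = integer(), dosage_sum = integer())
    calls <- data.frame(locus_id = character(), sample = character(),
                        haplotype = character(), dosage = integer())
  }
  rownames(calls) <- rownames(cells) <- NULL
  structure(list(calls = calls, cells = cells, samples = samples,
                 loci = loci, ploidy = as.integer(ploidy)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", length(x$loci), "loci x", length(x$samples),
      "samples;", nrow(x$cells), "non-missing cells\n")
  invisible(x)
}

#' Filter loci on completeness and correctness
#'
#' Retains a locus iff the fraction of samples with a non-missing, correct
#' cell (dosages summing to the ploidy) is strictly greater than
#' \code{completeness} AND the fraction of non-missing cells that are
#' correct is strictly greater than \code{correctness}. In retained loci,
#' incorrect cells are set MISSING. Scoring completeness on the cells that
#' survive downstream makes the filter idempotent: re-filtering its own
#' output never changes the result.
#'
#' @param dm A \code{dosage_matrix}.
#' @param completeness Strict lower bound on per-locus call completeness
#'   (default 0.9).
#' @param correctness Strict lower bound on per-locus call correctness
#'   (default 0.9).
#' @return The filtered \code{dosage_matrix} (its \code{loci} are the
#'   retained locus ids).
#' @export
filter_loci <- function(dm, completeness = 0.9, correctness = 0.9) {
  if (length(dm$loci) == 0L) stop("empty dosage matrix", call. = FALSE)
  n <- length(dm$samples)
  cells <- dm$cells
  n_cells <- table(factor(cells$locus_id, levels = dm$loci))
  good <- !is.na(cells$dosage_sum) & cells$dosage_sum == dm$ploidy
  n_good <- table(factor(cells$locus_id[good], levels = dm$loci))
  comp <- as.numeric(n_good) / n
  corr <- ifelse(n_cells > 0, as.numeric(n_good) / as.numeric(n_cells), 0)
  retained <- dm$loci[comp > completeness & corr > correctness]
  keep_cells <- cells$locus_id %in% retained & good
  cells2 <- cells[keep_cells, , drop = FALSE]
  cellkey <- paste(cells2$locus_id, cells2$sample, sep = "\r")
  callkey <- paste(dm$calls$locus_id, dm$calls$sample, sep = "\r")
  calls2 <- dm$calls[callkey %in% cellkey, , drop = FALSE]
  rownames(calls2) <- rownames(cells2) <- NULL
  structure(list(calls = calls2, cells = cells2, samples = dm$samples,
                 loci = retained, ploidy = dm$ploidy),
            class = "dosage_matrix")
}

#' Per-sample heterozygous-locus fraction
#'
#' Among a sample's non-missing, correct cells, the fraction carrying at
#' least two distinct haplotypes with dosage >= 1. Samples without data get
#' NA (not 0).
#'
#' @param dm A \code{dosage_matrix}.
#' @param sample Optional single sample name; default all samples.
#' @return Named numeric vector (or scalar if \code{sample} given).
#' @export
het_fraction <- function(dm, sample = NULL) {
  samples <- if (is.null(sample)) dm$samples else sample
  good <- dm$cells[!is.na(dm$cells$dosage_sum) &
                     dm$cells$dosage_sum == dm$ploidy, , drop = FALSE]
  calls <- dm$calls[!is.na(dm$calls$dosage) & dm$calls$dosage >= 1L, ,
                    drop = FALSE]
  nhap <- tapply(calls$haplotype,
                 paste(calls$locus_id, calls$sample, sep = "\r"),
                 function(h) length(unique(h)))
  out <- vapply(samples, function(s) {
    loci_s <- good$locus_id[good$sample == s]
    if (!length(loci_s)) return(NA_real_)
    cell_keys <- paste(loci_s, s, sep = "\r")
    k <- nhap[cell_keys]
    k[is.na(k)] <- 0
    mean(k >= 2)
  }, numeric(1))
  if (!is.null(sample)) unname(out[sample]) else out
}

#' Write / read the dosage table as TSV
#'
#' Wide layout: rows are (locus_id, haplotype) pairs, columns are samples,
#' values are discrete dosages (blank = absent or missing cell). A cell is
#' reconstructed as MISSING on read iff all of its locus' haplotype rows are
#' blank for that sample.
#'
#' @param dm A \code{dosage_matrix}.
#' @param path Output TSV path.
#' @export
write_dosage_tsv <- function(dm, path) {
  calls <- dm$calls
  keys <- unique(calls[, c("locus_id", "haplotype")])
  wide <- matrix(NA_integer_, nrow = nrow(keys), ncol = length(dm$samples),
                 dimnames = list(NULL, dm$samples))
  ri <- match(paste(calls$locus_id, calls$haplotype, sep = "\r"),
              paste(keys$locus_id, keys$haplotype, sep = "\r"))
  wide[cbind(ri, match(calls$sample, dm$samples))] <- calls$dosage
  out <- cbind(keys, as.data.frame(wide, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param ploidy Ploidy used to rebuild correctness on read (default 2).
#' @return \code{read_dosage_tsv} returns a \code{dosage_matrix}.
#' @export
read_dosage_tsv <- function(path, ploidy = 2L) {
  wide <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = c("character", "character"))
  samples <- colnames(wide)[-(1:2)]
  long <- do.call(rbind, lapply(samples, function(s) {
    v <- suppressWarnings(as.integer(wide[[s]]))
    keep <- !is.na(v)
    data.frame(locus_id = wide$locus_id[keep], sample = s,
               haplotype = wide$haplotype[keep], dosage = v[keep],
               stringsAsFactors = FALSE)
  }))
  key <- paste(long$locus_id, long$sample, sep = "\r")
  first <- !duplicated(key)
  ds <- tapply(long$dosage, key, sum)
  cells <- data.frame(locus_id = long$locus_id[first],
                      sample = long$sample[first], stringsAsFactors = FALSE)
  k <- paste(cells$locus_id, cells$sample, sep = "\r")
  cells$n_reads <- NA_integer_
  cells$dosage_sum <- as.integer(ds[k])
  calls <- long[long$dosage >= 1L, , drop = FALSE]
  rownames(calls) <- rownames(cells) <- NULL
  structure(list(calls = calls, cells = cells, samples = samples,
                 loci = unique(wide$locus_id), ploidy = as.integer(ploidy)),
            class = "dosage_matrix")
}

#' Write the haplotype read-count table as TSV
#'
#' @param counts Long count table from \code{\link{haplotype_count_table}}.
#' @param path Output TSV path.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "integer"))
}
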