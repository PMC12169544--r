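#' SNP call set container
#'
#' A \code{snp_set} couples a site table (contig, 1-based position, ref/alt
#' single-base alleles, and the five GATK-style site annotations) with a
#' genotype matrix coded as alt-allele dosage: 0 = hom-ref, 1 = het,
#' 2 = hom-alt, NA = missing.
#'
#' @param sites data.frame with columns \code{contig, pos, ref, alt} and
#'   optionally \code{QD, FS, SOR, MQ, MQRankSum} (numeric, NA allowed).
#' @param gt Integer matrix, rows parallel to \code{sites}, columns named by
#'   sample.
#' @return An object of class \code{snp_set}.
#' @export
snp_set <- function(sites, gt) {
  stopifnot(nrow(sites) == nrow(gt))
  if (nrow(gt) && is.null(colnames(gt))) stop("gt must have sample names")
  for (k in hard_filter_keys()) if (is.null(sites[[k]])) sites[[k]] <- NA_real_
  bad_allele <- nchar(sites$ref) != 1L | nchar(sites$alt) != 1L |
    sites$ref == sites$alt
  if (any(bad_allele)) stop("snp_set requires bi-allelic single-nucleotide sites")
  rownames(gt) <- site_ids(sites)
  structure(list(sites = sites, gt = gt), class = "snp_set")
}

site_ids <- function(sites) {
  if (nrow(sites) == 0L) return(character(0))
  paste0(sites$contig, ":", sites$pos)
}

hard_filter_keys <- function() c("QD", "FS", "SOR", "MQ", "MQRankSum")

#' @export
print.snp_set <- function(x, ...) {
  cat("snp_set:", nrow(x$sites), "bi-allelic SNPs x", ncol(x$gt), "samples\n")
  invisible(x)
}

subset_snp_set <- function(x, keep) {
  snp_set(x$sites[keep, , drop = FALSE], x$gt[keep, , drop = FALSE])
}

#' Read bi-allelic SNPs from a VCF
#'
#' Parses VCF v4.2 via \pkg{vcfR}; multi-allelic and indel records are
#' dropped with a message reporting the count. Genotypes are recoded to
#' alt-allele dosage; the INFO keys QD/FS/SOR/MQ/MQRankSum are extracted when
#' present. A present but non-numeric annotation raises an error naming the
#' record.
#'
#' @param path VCF file (plain text or gzipped).
#' @return A \code{\link{snp_set}}.
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep[is.na(keep)] <- FALSE
  if (any(!keep)) {
    message("dropped ", sum(!keep), " multi-allelic/indel record(s) on ingest")
  }
  sites <- data.frame(contig = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  for (k in hard_filter_keys()) {
    raw <- vcfR::extract.info(v, element = k)[keep]
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "." & is.na(val)
    if (any(bad)) {
      stop("malformed numeric annotation ", k, " at record ",
           site_ids(sites)[which(bad)[1]], call. = FALSE)
    }
    sites[[k]] <- val
  }
  gtc <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gtc))) gtc <- matrix(gtc, nrow = 1,
                                       dimnames = list(NULL, names(gtc)))
  gtc <- gtc[keep, , drop = FALSE]
  gt <- matrix(NA_integer_, nrow = nrow(sites), ncol = ncol(gtc),
               dimnames = list(NULL, colnames(gtc)))
  a1 <- substr(gtc, 1, 1); a2 <- substr(gtc, 3, 3)
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  gt[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  snp_set(sites, gt)
}

#' Write a snp_set as VCF v4.2
#'
#' @param x A \code{\link{snp_set}}.
#' @param path Output path.
#' @param filter Optional character vector of FILTER values per record
#'   (default PASS).
#' @export
write_snp_vcf <- function(x, path, filter = NULL) {
  n <- nrow(x$sites)
  if (is.null(filter)) filter <- rep("PASS", n)
  fmt_ann <- function(k) {
    v <- x$sites[[k]]
    ifelse(is.na(v), NA_character_, sprintf("%s=%.4g", k, v))
  }
  info <- apply(do.call(cbind, lapply(hard_filter_keys(), fmt_ann)), 1L,
                function(r) {
                  r <- r[!is.na(r)]
                  if (length(r)) paste(r, collapse = ";") else "."
                })
  if (n == 0L) info <- character(0)
  gtc <- matrix(c("0/0", "0/1", "1/1")[x$gt + 1L], nrow = n)
  gtc[is.na(gtc)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   hard_filter_keys(), hard_filter_keys()),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(x$gt)), collapse = "\t"))
  body <- character(0)
  if (n) {
    body <- paste(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT",
                          x$sites$contig, x$sites$pos, x$sites$ref,
                          x$sites$alt, filter, info),
                  apply(gtc, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Default hard-filter thresholds
#'
#' A record fails when QD < 2, FS > 60, SOR > 3, MQ < 40 or
#' MQRankSum < -8 (GATK best-practice site filters for SNPs).
#' @return Named list of thresholds.
#' @export
hard_filter_defaults <- function() {
  list(QD = 2.0, FS = 60.0, SOR = 3.0, MQ = 40.0, MQRankSum = -8.0)
}

#' Apply hard filters on site annotations
#'
#' A record fails if ANY present annotation violates its threshold; absent
#' (NA) annotations never fail a record. Fail reasons name the violated keys.
#'
#' @param x A \code{\link{snp_set}}.
#' @param thresholds Named list as \code{\link{hard_filter_defaults}}.
#' @return List: \code{retained} (snp_set), \code{removed} (snp_set),
#'   \code{reasons} (character per input record: "" or comma-separated
#'   violated keys, e.g. \code{"QD,FS"}).
#' @export
apply_hard_filters <- function(x, thresholds = hard_filter_defaults()) {
  n <- nrow(x$sites)
  viol <- matrix(FALSE, nrow = n, ncol = 5L,
                 dimnames = list(NULL, hard_filter_keys()))
  for (k in hard_filter_keys()) {
    v <- x$sites[[k]]
    if (!is.numeric(v)) stop("annotation ", k, " is not numeric", call. = FALSE)
    viol[, k] <- switch(k,
      QD = !is.na(v) & v < thresholds$QD,
      FS = !is.na(v) & v > thresholds$FS,
      SOR = !is.na(v) & v > thresholds$SOR,
      MQ = !is.na(v) & v < thresholds$MQ,
      MQRankSum = !is.na(v) & v < thresholds$MQRankSum)
  }
  reasons <- apply(viol, 1L, function(r) paste(colnames(viol)[r], collapse = ","))
  if (n == 0L) reasons <- character(0)
  fail <- reasons != ""
  list(retained = subset_snp_set(x, !fail),
       removed = subset_snp_set(x, fail),
       reasons = reasons)
}

#' Find singleton SNPs
#'
#' A singleton is a site heterozygous in exactly one sample while every other
#' non-missing sample carries the same homozygous genotype (all hom-ref or
#' all hom-alt).
#'
#' @param x A \code{\link{snp_set}}.
#' @return Character vector of singleton site ids (\code{"contig:pos"}).
#' @export
find_singletons <- function(x) {
  gt <- x$gt
  het <- rowSums(gt == 1L, na.rm = TRUE)
  hom0 <- rowSums(gt == 0L, na.rm = TRUE)
  hom2 <- rowSums(gt == 2L, na.rm = TRUE)
  is_singleton <- het == 1L & (hom0 == 0L | hom2 == 0L)
  site_ids(x$sites)[is_singleton]
}

#' Subset SNPs to frame loci
#'
#' Keeps records whose 1-based position falls inside a frame after converting
#' from the frames' 0-based half-open coordinates: position p is inside frame
#' \[start, end) iff start < p <= end.
#'
#' @param x A \code{\link{snp_set}}.
#' @param frames Frame data.frame (\code{\link{define_frames}} subset).
#' @return The subset \code{snp_set}.
#' @export
subset_to_loci <- function(x, frames) {
  if (nrow(frames) == 0L || nrow(x$sites) == 0L) {
    return(subset_snp_set(x, logical(nrow(x$sites))))
  }
  fr <- GenomicRanges::GRanges(frames$contig,
                               IRanges::IRanges(frames$start + 1L, frames$end))
  sn <- GenomicRanges::GRanges(x$sites$contig,
                               IRanges::IRanges(x$sites$pos, x$sites$pos))
  keep <- IRanges::overlapsAny(sn, fr)
  subset_snp_set(x, keep)
}

#' Naive pileup SNP caller for simulated data
#'
#' A deliberately simple majority-composition caller used on synthetic
#' alignments (real studies would use a haplotype-based caller and supply the
#' VCF directly). A site is emitted if in at least one sample two alleles each
#' reach \code{min_alt_fraction} of that sample's pileup. Per sample: missing
#' if depth < \code{min_depth}; het if both ref and alt pass the fraction;
#' hom for the single passing allele; missing when a third allele passes.
#' Site annotations are synthesized as pass-like constants.
#'
#' @param alignments Named list of per-sample \code{GAlignments} or BAM paths
#'   (paths are required here: pileups are computed by \pkg{Rsamtools}).
#' @param reference Reference \code{DNAStringSet}.
#' @param min_depth Minimum per-sample depth for a genotype call (default 8).
#' @param min_alt_fraction Minimum within-sample allele fraction (default 0.2).
#' @param min_mapq Minimum mapping quality for pileup inclusion (default 30).
#' @return A \code{\link{snp_set}}.
#' @export
naive_pileup_caller <- function(alignments, reference, min_depth = 8L,
                                min_alt_fraction = 0.2, min_mapq = 30L) {
  samples <- names(alignments)
  if (is.null(samples)) stop("alignments must be named by sample", call. = FALSE)
  pp <- Rsamtools::PileupParam(distinguish_strands = FALSE,
                               min_mapq = min_mapq, min_base_quality = 0L,
                               max_depth = 100000L,
                               distinguish_nucleotides = TRUE)
  counts <- lapply(alignments, function(p) {
    bf <- if (methods::is(p, "BamFile")) p else Rsamtools::BamFile(p)
    pu <- Rsamtools::pileup(bf, pileupParam = pp)
    pu$nucleotide <- as.character(pu$nucleotide)
    pu[pu$nucleotide %in% c("A", "C", "G", "T"), ]
  })

  ref_chars <- lapply(seq_along(reference), function(i) {
    strsplit(as.character(reference[[i]]), "")[[1]]
  })
  names(ref_chars) <- names(reference)

  bases <- c("A", "C", "G", "T")
  sites_list <- list()
  gt_list <- list()
  for (cg in names(reference)) {
    L <- length(ref_chars[[cg]])
    # per-sample position x base count matrices for this contig
    mats <- lapply(counts, function(pu) {
      pu <- pu[as.character(pu$seqnames) == cg, ]
      m <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, bases))
      if (nrow(pu)) m[cbind(pu$pos, match(pu$nucleotide, bases))] <- pu$count
      m
    })
    depth <- vapply(mats, rowSums, numeric(L))
    # candidate sites: some sample shows two alleles each >= min_alt_fraction
    cand <- rep(FALSE, L)
    for (s in samples) {
      d <- depth[, s]
      ok <- d >= min_depth
      frac_pass <- mats[[s]] >= pmax(d * min_alt_fraction, 1L)
      cand <- cand | (ok & rowSums(frac_pass) >= 2L)
    }
    pos <- which(cand)
    if (!length(pos)) next
    refb <- ref_chars[[cg]][pos]
    tot <- Reduce(`+`, mats)[pos, , drop = FALSE]
    altb <- vapply(seq_along(pos), function(i) {
      o <- tot[i, ]
      o[refb[i]] <- -1L
      bases[which.max(o)]
    }, character(1))
    gt <- matrix(NA_integer_, nrow = length(pos), ncol = length(samples),
                 dimnames = list(NULL, samples))
    for (s in samples) {
      d <- depth[pos, s]
      pass <- mats[[s]][pos, , drop = FALSE] >= pmax(d * min_alt_fraction, 1L)
      npass <- rowSums(pass)
      ref_pass <- pass[cbind(seq_along(pos), match(refb, bases))]
      alt_pass <- pass[cbind(seq_along(pos), match(altb, bases))]
      g <- rep(NA_integer_, length(pos))
      g[npass == 2L & ref_pass & alt_pass] <- 1L
      g[npass == 1L & ref_pass] <- 0L
      g[npass == 1L & alt_pass] <- 2L
      g[d < min_depth] <- NA_integer_
      gt[, s] <- g
    }
    sites_list[[cg]] <- data.frame(contig = cg, pos = pos, ref = refb,
                                   alt = altb, stringsAsFactors = FALSE)
    gt_list[[cg]] <- gt
  }
  if (!length(sites_list)) {
    return(snp_set(data.frame(contig = character(), pos = integer(),
                              ref = character(), alt = character()),
                   matrix(integer(), 0L, length(samples),
                          dimnames = list(NULL, samples))))
  }
  sites <- do.call(rbind, sites_list)
  rownames(sites) <- NULL
  sites$QD <- 25; sites$FS <- 0; sites$SOR <- 1
  sites$MQ <- 60; sites$MQRankSum <- 0
  snp_set(sites, do.call(rbind, gt_list))
}
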