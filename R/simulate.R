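#' Simulate a random reference sequence set
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{Biostrings::DNAStringSet} with \code{n_contigs} sequences of
#'   \code{contig_length} bp, named \code{contig_1 ... contig_n}. Deterministic
#'   given \code{config$seed}.
#' @examples
#' ref <- simulate_reference(sim_config(seed = 7, n_contigs = 2, contig_length = 1000))
#' Biostrings::width(ref)
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, 1L))
  seqs <- vapply(seq_len(config$n_contigs), function(i) {
    paste0(sample(c("A", "C", "G", "T"), config$contig_length, replace = TRUE),
           collapse = "")
  }, character(1))
  names(seqs) <- paste0("contig_", seq_len(config$n_contigs))
  Biostrings::DNAStringSet(seqs)
}

#' Simulate a structured diploid cohort (truth genotypes)
#'
#' Draws polymorphic sites at \code{snp_density}, assigns each site either a
#' fixed species difference (with probability \code{species_divergence}: alt
#' frequency 1 in species A, 0 in species B) or a shared polymorphism with a
#' common ancestral frequency drawn uniformly on \[0.1, 0.9\]; perturbs each
#' subpopulation's frequency by Normal(0, \code{subpop_drift}) clamped to
#' \[0,1\]; and draws each individual's two phased alleles as independent
#' Bernoulli trials at its subpopulation frequency. Species-B individuals draw
#' from the species-A frequency at a site with probability
#' \code{admixture_fraction}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param reference Reference \code{DNAStringSet} from
#'   \code{\link{simulate_reference}}.
#' @return A \code{truth_set}: list with \code{sites} (data.frame
#'   \code{contig, pos, ref, alt}; 1-based positions), phased allele matrices
#'   \code{allele1}/\code{allele2} (sites x samples, 0 = ref, 1 = alt),
#'   \code{labels} (data.frame \code{sample, species, subpop}), and
#'   \code{subpop_freq} (sites x subpops alt-allele frequencies).
#' @export
simulate_cohort <- function(config, reference) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, 2L))

  species <- c("A", "B")
  subpops <- as.vector(outer(seq_len(config$n_subpops_per_species), species,
                             function(i, s) paste0(s, i)))
  labels <- do.call(rbind, lapply(subpops, function(sp) {
    data.frame(
      sample = sprintf("%s-%02d", sp, seq_len(config$samples_per_subpop)),
      species = substr(sp, 1, 1), subpop = sp, stringsAsFactors = FALSE
    )
  }))

  # polymorphic sites per contig
  sites <- do.call(rbind, lapply(seq_along(reference), function(ci) {
    L <- Biostrings::width(reference)[ci]
    pos <- which(stats::runif(L) < config$snp_density)
    if (length(pos) == 0L) return(NULL)
    refb <- strsplit(as.character(reference[[ci]]), "")[[1]][pos]
    altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                   character(1), USE.NAMES = FALSE)
    data.frame(contig = names(reference)[ci], pos = pos, ref = refb, alt = altb,
               stringsAsFactors = FALSE)
  }))
  if (is.null(sites)) {
    sites <- data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character())
  }
  S <- nrow(sites)
  n <- nrow(labels)

  # species-level alt frequencies
  divergent <- stats::runif(S) < config$species_divergence
  p_shared <- stats::runif(S, 0.1, 0.9)
  pA <- ifelse(divergent, 1, p_shared)
  pB <- ifelse(divergent, 0, p_shared)

  # subpopulation frequencies: species frequency + drift, clamped
  sub_freq <- matrix(0, nrow = S, ncol = length(subpops),
                     dimnames = list(NULL, subpops))
  for (sp in subpops) {
    base <- if (substr(sp, 1, 1) == "A") pA else pB
    f <- base + stats::rnorm(S, 0, config$subpop_drift)
    sub_freq[, sp] <- pmin(pmax(f, 0), 1)
  }

  allele1 <- matrix(0L, nrow = S, ncol = n, dimnames = list(NULL, labels$sample))
  allele2 <- allele1
  if (S > 0L) {
    for (j in seq_len(n)) {
      f <- sub_freq[, labels$subpop[j]]
      if (labels$species[j] == "B" && config$admixture_fraction > 0) {
        adm <- stats::runif(S) < config$admixture_fraction
        f <- ifelse(adm, pA, f)
      }
      allele1[, j] <- as.integer(stats::runif(S) < f)
      allele2[, j] <- as.integer(stats::runif(S) < f)
    }
  }

  structure(list(sites = sites, allele1 = allele1, allele2 = allele2,
                 labels = labels, subpop_freq = sub_freq),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$sites), "variant sites x", nrow(x$labels),
      "samples (", length(unique(x$labels$subpop)), "subpops )\n")
  invisible(x)
}

# truth genotypes coded 0/1/2 (alt-allele dosage)
truth_genotypes <- function(truth) truth$allele1 + truth$allele2

bases_at <- function(chars, idx) chars[idx]

# substitute alt alleles into a reference character vector
apply_alleles <- function(ref_chars, pos, alt, carried) {
  out <- ref_chars
  k <- which(carried == 1L)
  if (length(k)) out[pos[k]] <- alt[k]
  out
}

#' Simulate aligned reads and a truth VCF
#'
#' Per sample and contig, draws a Poisson number of reads with expected
#' per-position depth \code{mean_depth}, uniform start positions, each read
#' copied from one of the individual's two phased chromosome copies (so
#' neighbouring heterozygous sites on one read are in true phase), then
#' applies uniform per-base miscalls at \code{error_rate}. Alignment records
#' carry the exact position, a full-length match CIGAR and \code{mapq};
#' per-sample SAM files are coordinate-sorted and converted to indexed BAM.
#' The truth VCF lists all variant sites with phased per-sample genotypes and
#' INFO annotations QD/FS/SOR/MQ/MQRankSum drawn from pass-like and fail-like
#' mixtures (\code{fail_annotation_rate}).
#'
#' @param truth A \code{truth_set} from \code{\link{simulate_cohort}}.
#' @param reference The reference \code{DNAStringSet}.
#' @param config The \code{\link{sim_config}} used to build \code{truth}.
#' @param dir Output directory (created if needed).
#' @return List with \code{bam} (named vector of per-sample BAM paths),
#'   \code{sam} (the SAM sources), and \code{vcf} (truth VCF path).
#' @export
simulate_reads <- function(truth, reference, config, dir) {
  validate_sim_config(config)
  if (config$read_length > config$contig_length) {
    stop("read_length (", config$read_length,
         ") exceeds contig_length (", config$contig_length, ")", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(child_seed(config$seed, 3L))

  R <- config$read_length
  contigs <- names(reference)
  seqlens <- stats::setNames(Biostrings::width(reference), contigs)
  ref_chars <- lapply(contigs, function(cg) {
    strsplit(as.character(reference[[cg]]), "")[[1]]
  })
  names(ref_chars) <- contigs

  # alternatives per base for miscalls
  alt_tab <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))

  samples <- truth$labels$sample
  sam_paths <- bam_paths <- stats::setNames(character(length(samples)), samples)

  for (j in seq_along(samples)) {
    smp <- samples[j]
    recs <- vector("list", length(contigs))
    for (ci in seq_along(contigs)) {
      cg <- contigs[ci]
      on_cg <- which(truth$sites$contig == cg)
      copy1 <- paste0(apply_alleles(ref_chars[[cg]], truth$sites$pos[on_cg],
                                    truth$sites$alt[on_cg],
                                    truth$allele1[on_cg, j]), collapse = "")
      copy2 <- paste0(apply_alleles(ref_chars[[cg]], truth$sites$pos[on_cg],
                                    truth$sites$alt[on_cg],
                                    truth$allele2[on_cg, j]), collapse = "")
      L <- seqlens[[cg]]
      n_reads <- stats::rpois(1L, config$mean_depth * L / R)
      if (n_reads == 0L) next
      starts <- sample.int(L - R + 1L, n_reads, replace = TRUE)
      copy <- sample(1:2, n_reads, replace = TRUE)
      seqs <- substring(c(copy1, copy2)[copy], starts, starts + R - 1L)
      seqs <- miscall_bases(seqs, R, config$error_rate, alt_tab)
      o <- order(starts)
      recs[[ci]] <- data.frame(
        qname = sprintf("%s_%s_r%06d", smp, cg, seq_len(n_reads)),
        rname = cg, pos = starts[o], seq = seqs[o], stringsAsFactors = FALSE
      )
    }
    recs <- do.call(rbind, recs)
    sam <- file.path(dir, paste0(smp, ".sam"))
    write_sam(recs, seqlens, sam, mapq = config$mapq, read_length = R)
    bam_paths[smp] <- Rsamtools::asBam(sam, file.path(dir, smp),
                                       overwrite = TRUE, indexDestination = TRUE)
    sam_paths[smp] <- sam
  }

  vcf <- file.path(dir, "truth.vcf")
  write_truth_vcf(truth, config, seqlens, vcf)
  list(bam = bam_paths, sam = sam_paths, vcf = vcf)
}

# apply uniform miscalls; processes k-th error per read in vectorized rounds
miscall_bases <- function(seqs, read_length, error_rate, alt_tab) {
  if (error_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), read_length, error_rate)
  idx <- which(n_err > 0L)
  if (!length(idx)) return(seqs)
  ri <- rep(idx, n_err[idx])
  pj <- unlist(lapply(n_err[idx], function(k) sample.int(read_length, k)))
  occ <- stats::ave(ri, ri, FUN = seq_along)
  for (r in seq_len(max(occ))) {
    sel <- occ == r
    i <- ri[sel]; p <- pj[sel]
    orig <- substr(seqs[i], p, p)
    sub <- alt_tab[cbind(match(orig, rownames(alt_tab)),
                         sample.int(3L, length(i), replace = TRUE))]
    s <- seqs[i]
    substr(s, p, p) <- sub
    seqs[i] <- s
  }
  seqs
}

# minimal coordinate-sorted SAM writer for simulated full-match records
write_sam <- function(recs, seqlens, path, mapq, read_length) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), unname(seqlens)))
  body <- character(0)
  if (!is.null(recs) && nrow(recs)) {
    qual <- strrep("I", read_length)
    body <- sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                    recs$qname, recs$rname, recs$pos, mapq, read_length,
                    recs$seq, qual)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_truth_vcf <- function(truth, config, seqlens, path) {
  set.seed(child_seed(config$seed, 4L))
  S <- nrow(truth$sites)
  ann <- simulate_annotations(S, config$fail_annotation_rate)
  info <- if (S) sprintf("QD=%.3f;FS=%.3f;SOR=%.3f;MQ=%.3f;MQRankSum=%.3f",
                         ann$QD, ann$FS, ann$SOR, ann$MQ, ann$MQRankSum)
          else character(0)
  gt <- matrix(paste0(truth$allele1, "|", truth$allele2), nrow = S)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(seqlens), unname(seqlens)),
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", truth$labels$sample), collapse = "\t"))
  body <- character(0)
  if (S) {
    fixed <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s\tGT",
                     truth$sites$contig, truth$sites$pos, truth$sites$ref,
                     truth$sites$alt, info)
    body <- paste(fixed, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# pass-like / fail-like mixture for the five site annotations; a fail-like
# site violates exactly one randomly chosen hard-filter threshold
simulate_annotations <- function(n, fail_rate) {
  ann <- data.frame(QD = stats::runif(n, 10, 35),
                    FS = stats::runif(n, 0, 5),
                    SOR = stats::runif(n, 0.5, 2.5),
                    MQ = stats::runif(n, 55, 60),
                    MQRankSum = stats::runif(n, -1, 1))
  fails <- which(stats::runif(n) < fail_rate)
  if (length(fails)) {
    key <- sample(c("QD", "FS", "SOR", "MQ", "MQRankSum"), length(fails),
                  replace = TRUE)
    for (i in seq_along(fails)) {
      r <- fails[i]
      ann[r, key[i]] <- switch(key[i],
        QD = stats::runif(1, 0, 1.9), FS = stats::runif(1, 61, 100),
        SOR = stats::runif(1, 3.1, 6), MQ = stats::runif(1, 20, 39.5),
        MQRankSum = stats::runif(1, -12, -8.1))
    }
  }
  ann
}

#' Simulate a complete dataset on disk
#'
#' Convenience wrapper: reference FASTA, per-sample coordinate-sorted BAM,
#' truth VCF and a population-label TSV, all under \code{dir}.
#'
#' @inheritParams simulate_reads
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory.
#' @return List: \code{config}, \code{truth}, \code{reference}, and paths
#'   \code{fasta}, \code{bam}, \code{vcf}, \code{labels}.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  fasta <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(reference, fasta)
  truth <- simulate_cohort(config, reference)
  aln_dir <- file.path(dir, "alignments")
  files <- simulate_reads(truth, reference, config, aln_dir)
  labels <- file.path(dir, "labels.tsv")
  utils::write.table(truth$labels, labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(config = config, truth = truth, reference = reference, fasta = fasta,
       bam = files$bam, sam = files$sam, vcf = files$vcf, labels = labels)
}
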