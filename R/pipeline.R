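#' Pipeline configuration
#'
#' Bundles the input paths and every stage parameter, with defaults equal to
#' the fingerprinting workflow's standard settings: 40-bp contiguous sliding
#' frames, 8 spanning reads minimum, >90 percent locus completeness, mapping
#' quality 30, 10 percent haplotype-frequency noise floor, dosage bounds
#' 15/15/85/85 for a diploid, >90 percent locus correctness, 50-kb diversity
#' windows and 200 bootstrap replicates.
#'
#' @param reference Reference FASTA path or \code{DNAStringSet}.
#' @param alignments Named vector of per-sample BAM paths.
#' @param outdir Output directory.
#' @param assignment Named character vector sample -> population, or a TSV
#'   with columns \code{sample} and \code{pop}.
#' @param vcf Optional VCF of bi-allelic SNPs; when NULL SNPs are called from
#'   the alignments with \code{\link{naive_pileup_caller}}.
#' @param frame_size,frame_distance Frame geometry in bp.
#' @param min_depth Minimum spanning reads per locus per sample.
#' @param completeness,correctness Strict per-locus fraction thresholds.
#' @param min_mapq Minimum mapping quality.
#' @param min_read_count,min_freq_pct,bounds,ploidy Dosage-calling controls
#'   (see \code{\link{call_dosage}}).
#' @param window_size Nucleotide-diversity window in bp.
#' @param n_bootstrap JID bootstrap replicates.
#' @param seed Seed for the locus bootstrap.
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(reference, alignments, outdir, assignment,
                            vcf = NULL,
                            frame_size = 40L, frame_distance = 40L,
                            min_depth = 8L, completeness = 0.9,
                            min_mapq = 30L, min_read_count = 8L,
                            min_freq_pct = 10, bounds = c(15, 15, 85, 85),
                            ploidy = 2L, correctness = 0.9,
                            window_size = 50000L, n_bootstrap = 200L,
                            seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("completeness", "correctness")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("invalid pipeline_config field '", f, "': must be in [0, 1]",
           call. = FALSE)
    }
  }
  if (frame_size < 1L || frame_distance < frame_size) {
    stop("invalid frame geometry", call. = FALSE)
  }
  if (n_bootstrap < 0L) stop("n_bootstrap must be >= 0", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

read_assignment <- function(assignment) {
  if (is.character(assignment) && length(assignment) == 1L &&
      file.exists(assignment)) {
    d <- utils::read.table(assignment, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    pop_col <- intersect(c("pop", "population", "subpop"), colnames(d))[1]
    assignment <- stats::setNames(d[[pop_col]], d$sample)
  }
  assignment
}

#' Run the full fingerprinting pipeline
#'
#' Stages: frame definition, spanning-depth locus selection, SNP
#' ingest/calling, hard filtering, read-backed haplotyping, dosage calling,
#' locus completeness/correctness filtering, SNP subsetting and singleton
#' detection, population-genetic estimators (Ho/Hs/FIS, windowed pi,
#' pairwise Nei FST, PCA), pairwise JID with locus bootstrap, and a
#' Neighbor-Joining tree with bipartition supports. Every intermediate is
#' written under \code{config$outdir} together with a JSON manifest of
#' parameters and per-stage record counts.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return (invisibly) a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$alignments,
              if (is.character(config$reference)) config$reference,
              if (is.character(config$vcf)) config$vcf)) {
    if (!file.exists(p)) stop("missing input path: ", p, call. = FALSE)
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reference <- if (is.character(config$reference)) {
    Biostrings::readDNAStringSet(config$reference)
  } else config$reference
  names(reference) <- sub("\\s.*$", "", names(reference))
  assignment <- read_assignment(config$assignment)

  frames <- define_frames(reference, config$frame_size, config$frame_distance)
  write_frames_bed(frames, file.path(outdir, "frames.bed"))

  aln <- as_alignment_list(as.list(config$alignments))
  depth <- spanning_depth_matrix(frames, aln, config$min_mapq)
  utils::write.table(data.frame(locus_id = rownames(depth), depth,
                                check.names = FALSE),
                     file.path(outdir, "spanning_depth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  selected <- select_loci(frames, depth, config$min_depth,
                          config$completeness)
  write_frames_bed(selected, file.path(outdir, "selected_loci.bed"))

  snps_raw <- if (is.null(config$vcf)) {
    naive_pileup_caller(config$alignments, reference,
                        min_depth = config$min_read_count,
                        min_mapq = config$min_mapq)
  } else if (is.character(config$vcf)) {
    read_snp_vcf(config$vcf)
  } else config$vcf
  hf <- apply_hard_filters(snps_raw)
  filt_col <- ifelse(hf$reasons == "", "PASS", gsub(",", ";", hf$reasons))
  write_snp_vcf(snps_raw, file.path(outdir, "snps_raw.vcf"), filter = filt_col)
  write_snp_vcf(hf$retained, file.path(outdir, "snps_filtered.vcf"))

  snps_sel <- subset_to_loci(hf$retained, selected)
  counts <- haplotype_count_table(selected, snps_sel$sites, aln,
                                  config$min_mapq)
  write_counts_tsv(counts, file.path(outdir, "haplotype_counts.tsv"))
  dm <- dosage_call_table(counts, samples = names(config$alignments),
                          loci = selected$locus_id,
                          min_read_count = config$min_read_count,
                          min_freq_pct = config$min_freq_pct,
                          bounds = config$bounds, ploidy = config$ploidy)
  dmf <- filter_loci(dm, config$completeness, config$correctness)
  write_dosage_tsv(dmf, file.path(outdir, "dosage.tsv"))
  retained_frames <- selected[selected$locus_id %in% dmf$loci, , drop = FALSE]
  write_frames_bed(retained_frames, file.path(outdir, "retained_loci.bed"))

  snps_final <- subset_to_loci(snps_sel, retained_frames)
  write_snp_vcf(snps_final, file.path(outdir, "snps_in_retained_loci.vcf"))
  singletons <- find_singletons(snps_final)

  pops <- het_stats(snps_final$gt, assignment)
  pops$pi <- vapply(pops$pop, function(p) {
    windowed_pi(snps_final, config$window_size,
                samples = names(assignment)[assignment == p])$mean_pi
  }, numeric(1))
  utils::write.table(pops, file.path(outdir, "popgen_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fst <- pairwise_neifst(snps_final$gt, assignment)
  write_distance_tsv(fst, file.path(outdir, "fst.tsv"))
  pca <- genotype_pca(snps_final$gt)
  utils::write.table(
    data.frame(sample = rownames(pca$scores),
               pca$scores[, seq_len(min(4L, ncol(pca$scores))), drop = FALSE]),
    file.path(outdir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  hetfrac <- het_fraction(dmf)
  utils::write.table(data.frame(sample = names(hetfrac),
                                het_fraction = unname(hetfrac)),
                     file.path(outdir, "het_fraction.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  J <- jid_matrix(dmf)
  write_distance_tsv(J, file.path(outdir, "jid.tsv"))
  tree <- NULL
  if (!any(is.na(J)) && nrow(J) >= 3L) {
    tree <- suppressMessages(nj_tree(J))
    if (config$n_bootstrap > 0L) {
      boots <- bootstrap_jid(dmf, config$n_bootstrap, config$seed)
      tree <- bootstrap_support(tree, boots)
    }
    write_newick(tree, file.path(outdir, "nj_tree.nwk"))
  }

  n_hap <- nrow(unique(dmf$calls[, c("locus_id", "haplotype")]))
  manifest <- list(
    parameters = config[setdiff(names(config), c("reference", "alignments",
                                                 "vcf", "assignment"))],
    samples = names(config$alignments),
    stage_counts = list(
      n_frames = nrow(frames),
      n_selected_loci = nrow(selected),
      n_snps_raw = nrow(snps_raw$sites),
      n_snps_failed_filter = nrow(hf$removed$sites),
      n_snps_pass_filter = nrow(hf$retained$sites),
      n_snps_in_selected_loci = nrow(snps_sel$sites),
      n_loci_retained = length(dmf$loci),
      n_haplotypes = n_hap,
      mean_haplotypes_per_locus = if (length(dmf$loci)) {
        n_hap / length(dmf$loci)
      } else NA,
      n_snps_in_retained_loci = nrow(snps_final$sites),
      n_singleton_snps = length(singletons),
      n_non_singleton_snps = nrow(snps_final$sites) - length(singletons)
    )
  )
  class(manifest$parameters) <- NULL
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(frames = frames, depth = depth, selected = selected,
                 snps_raw = snps_raw, hard_filter = hf,
                 snps_selected = snps_sel, counts = counts, dosage = dm,
                 dosage_filtered = dmf, snps_final = snps_final,
                 singletons = singletons, pop_stats = pops, fst = fst,
                 pca = pca, het_fraction = hetfrac, jid = J, tree = tree,
                 manifest = manifest))
}

#' Simulate a dataset and run the pipeline on it
#'
#' @param sim A \code{\link{sim_config}}.
#' @param outdir Output directory (dataset under \code{data/}, results under
#'   \code{results/}).
#' @param use_truth_vcf Use the simulator's truth VCF as SNP input instead of
#'   the naive pileup caller (default FALSE).
#' @param ... Overrides passed to \code{\link{pipeline_config}}.
#' @return List: \code{dataset} (see \code{\link{simulate_dataset}}) and
#'   \code{result} (see \code{\link{run_pipeline}}).
#' @export
run_synthetic_pipeline <- function(sim, outdir, use_truth_vcf = FALSE, ...) {
  ds <- simulate_dataset(sim, file.path(outdir, "data"))
  assignment <- stats::setNames(ds$truth$labels$subpop, ds$truth$labels$sample)
  cfg <- pipeline_config(reference = ds$fasta, alignments = ds$bam,
                         outdir = file.path(outdir, "results"),
                         assignment = assignment,
                         vcf = if (use_truth_vcf) ds$vcf else NULL,
                         seed = sim$seed, ...)
  list(dataset = ds, result = run_pipeline(cfg))
}
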