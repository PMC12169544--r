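# Shared fixtures. The two simulated cohorts are expensive, so they are
# built once per test session and cached.

fixture_env <- new.env(parent = emptyenv())

# Default study conditions: 2 species x 2 subpops x 5 samples, 2 x 50 kb,
# 30x, 0.2% error, 200 JID bootstrap replicates.
default_run <- function() {
  if (is.null(fixture_env$default)) {
    dir <- file.path(tempdir(), "shorthap-default-run")
    fixture_env$default <- run_synthetic_pipeline(sim_config(seed = 101L), dir)
  }
  fixture_env$default
}

# Error-free high-depth cohort for exact-recovery checks: 12 samples x
# 100 kb at 70x, no miscalls, no bootstrap.
exact_run <- function() {
  if (is.null(fixture_env$exact)) {
    dir <- file.path(tempdir(), "shorthap-exact-run")
    cfg <- sim_config(seed = 202L, samples_per_subpop = 3L, mean_depth = 70,
                      error_rate = 0)
    fixture_env$exact <- run_synthetic_pipeline(cfg, dir, n_bootstrap = 0L)
  }
  fixture_env$exact
}

# Write a small SAM file from explicit read tuples (pos 1-based).
write_test_sam <- function(reads, seqlens, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), unname(seqlens)))
  o <- order(reads$rname, reads$pos)
  reads <- reads[o, , drop = FALSE]
  body <- sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$rname, reads$pos, reads$mapq,
                  reads$cigar, reads$seq, strrep("I", nchar(reads$seq)))
  writeLines(c(hdr, body), path)
  path
}

# Expected per-sample truth haplotype dosages for one frame, built from the
# phased truth alleles at the given (called) SNP positions.
truth_frame_dosage <- function(truth, contig, snp_pos, sample_idx) {
  rows <- match(paste(contig, snp_pos), paste(truth$sites$contig, truth$sites$pos))
  base_of <- function(allele_vec) {
    paste(ifelse(allele_vec == 1L, truth$sites$alt[rows],
                 truth$sites$ref[rows]), collapse = "")
  }
  h1 <- base_of(truth$allele1[rows, sample_idx])
  h2 <- base_of(truth$allele2[rows, sample_idx])
  if (h1 == h2) stats::setNames(2L, h1) else
    stats::setNames(c(1L, 1L), sort(c(h1, h2)))
}
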