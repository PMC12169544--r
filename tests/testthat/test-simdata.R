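test_that("reference simulation honours lengths and is deterministic", {
  cfg <- sim_config(seed = 7, n_contigs = 2, contig_length = 1000)
  ref <- simulate_reference(cfg)
  expect_length(ref, 2L)
  expect_equal(unname(Biostrings::width(ref)), c(1000L, 1000L))
  expect_identical(as.character(ref), as.character(simulate_reference(cfg)))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(contig_length = 0), "contig_length")
  expect_error(sim_config(snp_density = 1.5), "snp_density")
  expect_error(sim_config(error_rate = -0.1), "error_rate")
  expect_error(sim_config(samples_per_subpop = 2.5), "samples_per_subpop")
})

test_that("degenerate cohorts behave as specified", {
  cfg <- sim_config(seed = 3, n_contigs = 1, contig_length = 5000,
                    species_divergence = 1, subpop_drift = 0,
                    admixture_fraction = 0, samples_per_subpop = 2)
  ref <- simulate_reference(cfg)
  truth <- simulate_cohort(cfg, ref)
  g <- truth$allele1 + truth$allele2
  spA <- truth$labels$sample[truth$labels$species == "A"]
  spB <- truth$labels$sample[truth$labels$species == "B"]
  # fixed difference at every site, identical within species
  expect_true(all(g[, spA] == 2L))
  expect_true(all(g[, spB] == 0L))

  cfg0 <- sim_config(seed = 3, n_contigs = 1, contig_length = 5000,
                     snp_density = 0)
  truth0 <- simulate_cohort(cfg0, simulate_reference(cfg0))
  expect_equal(nrow(truth0$sites), 0L)
})

test_that("between-species genotype difference matches the closed-form expectation", {
  cfg <- sim_config(seed = 11, subpop_drift = 0, admixture_fraction = 0)
  truth <- simulate_cohort(cfg, simulate_reference(cfg))
  a <- which(truth$labels$species == "A")[1]
  b <- which(truth$labels$species == "B")[1]
  g <- truth$allele1 + truth$allele2
  emp <- mean(g[, a] != g[, b])
  expe <- oracle_expected_geno_diff(cfg$species_divergence)
  S <- nrow(truth$sites)
  expect_gt(S, 500)
  expect_lt(abs(emp - expe), 3 * sqrt(expe * (1 - expe) / S))
})

test_that("truth heterozygosity per subpopulation matches 2f(1-f)", {
  cfg <- sim_config(seed = 13)
  truth <- simulate_cohort(cfg, simulate_reference(cfg))
  het <- truth$allele1 != truth$allele2
  S <- nrow(truth$sites)
  for (sp in colnames(truth$subpop_freq)) {
    smp <- truth$labels$sample[truth$labels$subpop == sp]
    f <- truth$subpop_freq[, sp]
    expect_lt(abs(mean(het[, smp]) - mean(2 * f * (1 - f))),
              3 * sqrt(0.25 / (S * length(smp))) + 3 * sqrt(0.25 / S))
  }
})

test_that("simulated reads carry truth alleles and expected depth", {
  # error-free homozygous-alt and heterozygous checks via the pileup
  cfg <- sim_config(seed = 5, n_contigs = 1, contig_length = 10000,
                    samples_per_subpop = 1, n_subpops_per_species = 1,
                    error_rate = 0, mean_depth = 40)
  ref <- simulate_reference(cfg)
  truth <- simulate_cohort(cfg, ref)
  dir <- file.path(tempdir(), "simreads-check")
  files <- simulate_reads(truth, ref, cfg, dir)
  g <- truth$allele1 + truth$allele2

  s <- truth$labels$sample[1]
  pp <- Rsamtools::PileupParam(distinguish_strands = FALSE,
                               min_base_quality = 0L,
                               distinguish_nucleotides = TRUE)
  pu <- Rsamtools::pileup(Rsamtools::BamFile(files$bam[[s]]), pileupParam = pp)
  hom_alt <- which(g[, s] == 2L)[1]
  if (!is.na(hom_alt)) {
    at <- pu[pu$pos == truth$sites$pos[hom_alt], ]
    expect_equal(as.character(at$nucleotide[which.max(at$count)]),
                 truth$sites$alt[hom_alt])
    expect_equal(sum(at$count[as.character(at$nucleotide) !=
                                truth$sites$alt[hom_alt]]), 0L)
  }
  het <- which(g[, s] == 1L)
  frac <- vapply(het, function(i) {
    at <- pu[pu$pos == truth$sites$pos[i], ]
    n <- sum(at$count)
    sum(at$count[as.character(at$nucleotide) == truth$sites$alt[i]]) / n
  }, numeric(1))
  # pooled alt fraction at het sites is binomial around 1/2
  tot_depth <- sum(vapply(het, function(i) {
    sum(pu$count[pu$pos == truth$sites$pos[i]])
  }, numeric(1)))
  expect_lt(abs(mean(frac) - 0.5), 4 * sqrt(0.25 / tot_depth) + 0.02)

  # mean per-position depth near mean_depth (Poisson read count)
  depth_mean <- sum(pu$count) / cfg$contig_length
  lambda <- cfg$mean_depth * cfg$contig_length / cfg$read_length
  sd_mean <- sqrt(lambda) * cfg$read_length / cfg$contig_length
  expect_lt(abs(depth_mean - cfg$mean_depth), 3 * sd_mean + 0.5)
})

test_that("read simulation rejects reads longer than the contig", {
  cfg <- sim_config(seed = 1, n_contigs = 1, contig_length = 100,
                    read_length = 150)
  ref <- simulate_reference(cfg)
  truth <- simulate_cohort(cfg, ref)
  expect_error(simulate_reads(truth, ref, cfg, tempdir()), "read_length")
})

test_that("identical seed and config give byte-identical FASTA/SAM/VCF", {
  cfg <- sim_config(seed = 9, n_contigs = 1, contig_length = 4000,
                    samples_per_subpop = 1, n_subpops_per_species = 1,
                    mean_depth = 10)
  d1 <- simulate_dataset(cfg, file.path(tempdir(), "det1"))
  d2 <- simulate_dataset(cfg, file.path(tempdir(), "det2"))
  md5 <- function(p) unname(tools::md5sum(p))
  expect_identical(md5(d1$fasta), md5(d2$fasta))
  expect_identical(md5(d1$vcf), md5(d2$vcf))
  expect_identical(vapply(d1$sam, md5, character(1), USE.NAMES = FALSE),
                   vapply(d2$sam, md5, character(1), USE.NAMES = FALSE))
})
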