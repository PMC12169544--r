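#' Simulation configuration for a hierarchically structured diploid cohort
#'
#' Parameterizes the synthetic cohort used to exercise the fingerprinting
#' pipeline end to end: a random reference, two diverged ancestral groups
#' ("species" A and B) each split into nested subpopulations, phased diploid
#' genotypes, and uniformly sampled error-prone reads emitted as aligned
#' records. Defaults describe two 50-kb contigs sequenced at 30x with 150-bp
#' reads, matching a whole-genome shotgun design at reduced scale.
#'
#' @param seed Integer seed; all randomness in the simulator flows from it
#'   (sub-stages derive child seeds deterministically).
#' @param n_contigs Number of reference contigs.
#' @param contig_length Length of each contig in bp.
#' @param snp_density Fraction of reference positions that are polymorphic.
#' @param species_divergence Probability that a polymorphic site is fixed
#'   different between species A and B (alt allele frequency 1 in A, 0 in B,
#'   before drift/admixture).
#' @param n_subpops_per_species Number of nested subpopulations per species.
#' @param subpop_drift Standard deviation of the per-site allele-frequency
#'   perturbation applied to each subpopulation (clamped to \[0,1\]).
#' @param admixture_fraction Per-site probability that a species-B individual
#'   draws its genotype from the species-A allele frequency.
#' @param samples_per_subpop Diploid individuals per subpopulation.
#' @param read_length Read length in bp.
#' @param mean_depth Expected read depth per position.
#' @param error_rate Per-base miscall probability.
#' @param mapq Mapping quality reported on every simulated alignment record.
#' @param fail_annotation_rate Fraction of truth-VCF sites given fail-like
#'   site annotations (one of QD/FS/SOR/MQ/MQRankSum drawn beyond its
#'   hard-filter threshold), so the filtering stage sees both outcomes.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7, n_contigs = 1, contig_length = 2000)
#' cfg$samples_per_subpop
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_length = 50000L,
                       snp_density = 0.02,
                       species_divergence = 0.3,
                       n_subpops_per_species = 2L,
                       subpop_drift = 0.15,
                       admixture_fraction = 0,
                       samples_per_subpop = 5L,
                       read_length = 150L,
                       mean_depth = 30,
                       error_rate = 0.002,
                       mapq = 60L,
                       fail_annotation_rate = 0.1) {
  cfg <- list(
    seed = seed, n_contigs = n_contigs, contig_length = contig_length,
    snp_density = snp_density, species_divergence = species_divergence,
    n_subpops_per_species = n_subpops_per_species, subpop_drift = subpop_drift,
    admixture_fraction = admixture_fraction,
    samples_per_subpop = samples_per_subpop, read_length = read_length,
    mean_depth = mean_depth, error_rate = error_rate, mapq = mapq,
    fail_annotation_rate = fail_annotation_rate
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid sim_config field '", field, "': ", what, call. = FALSE)
  }
  for (f in c("snp_density", "species_divergence", "subpop_drift",
              "admixture_fraction", "error_rate", "fail_annotation_rate")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0, 1]")
  }
  for (f in c("n_contigs", "contig_length", "n_subpops_per_species",
              "samples_per_subpop", "read_length")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 1 && cfg[[f]] == round(cfg[[f]]), f,
        "must be a positive integer")
  }
  chk(num1(cfg$mean_depth) && cfg$mean_depth > 0, "mean_depth", "must be positive")
  chk(num1(cfg$mapq) && cfg$mapq >= 0, "mapq", "must be non-negative")
  chk(num1(cfg$seed) && cfg$seed == round(cfg$seed), "seed", "must be an integer")
  invisible(cfg)
}

# Deterministic child seed per simulation stage, kept below 2^31.
child_seed <- function(seed, stage) {
  (abs(as.numeric(seed)) * 7919 + 104729 * stage) %% 2147483629
}

#' @export
print.sim_config <- function(x, ...) {
  n <- 2L * x$n_subpops_per_species * x$samples_per_subpop
  cat("sim_config:", x$n_contigs, "contig(s) x", x$contig_length, "bp;",
      n, "samples (2 species x", x$n_subpops_per_species, "subpops x",
      x$samples_per_subpop, "); depth", x$mean_depth, "x; seed", x$seed, "\n")
  invisible(x)
}
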