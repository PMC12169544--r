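---
title: "Methods: read-backed short-haplotype fingerprinting"
author: "shorthap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-backed short-haplotype fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
`shorthap`, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the method description left
room.

## The marker model

`shorthap` genotypes diploid individuals at *short multi-allelic haplotype
markers* built from whole-genome shotgun alignments against a (possibly
fragmented) reference assembly.

The reference is tiled with **sliding frames**: fixed-width intervals
(default 40 bp) placed start-to-start at a fixed distance (default 40 bp,
i.e. contiguous and non-overlapping). Each frame is one candidate locus.
Frames are 0-based half-open internally and in BED output; VCF positions
are converted from 1-based on read.

Within a frame, the bases that one read carries at the frame's SNP
positions, concatenated in coordinate order, form a **haplotype string**.
Because all SNPs of a frame are read from the *same* read, neighbouring
SNPs are phased by physical linkage — no statistical phasing across
samples, no linkage-disequilibrium model. This is the central assumption:
a read that completely spans a frame is an observation of one of the
individual's two chromosome copies at that locus. Reads therefore only
count when they

* completely span the frame (no partial overlap),
* have mapping quality at least `min_mapq` (default 30),
* and carry no insertion or deletion overlapping the frame (haplotype
  strings are defined on the reference coordinate system; an indel inside
  the frame would make the string ambiguous). Base qualities are not
  consulted; only mapping quality is.

A frame with zero SNP positions yields a single monomorphic haplotype,
written as `"."`; such loci are legitimate (every cohort-wide marker table
contains monomorphic loci) and flow through filtering with dosage
`{".": 2}`.

## Discrete dosage calling

For each (locus, sample) cell, haplotype read counts are converted to
discrete allele dosages:

* cells with fewer than `min_read_count` (8) total reads are **missing**;
* each haplotype's frequency is its percentage of the *total* cell count.
  Haplotypes below the `min_freq_pct` (10%) noise floor are treated as
  absent. Frequencies are deliberately *not* renormalized after removing
  sub-threshold haplotypes: the floor models sequencing-error alleles, and
  renormalizing would shift genuine allele frequencies by an amount that
  depends on the error load of the cell;
* remaining frequencies map to dosages through the interval bounds
  `(b1, b2, b3, b4) = (15, 15, 85, 85)` percent: `f < b1` → 0,
  `b2 ≤ f ≤ b3` → 1, `f > b4` → 2. With the default bounds the intervals
  are exhaustive; if a user supplies bounds with open gaps
  (`b1 < b2` or `b3 < b4`), a frequency inside a gap gets an *undefined*
  dosage (NA), which marks the cell incorrect rather than guessing.

A cell is **correct** when its defined dosages sum to the ploidy (2): the
diploid has been observed as exactly two allele copies. The bounds encode a
binomial argument: a true heterozygote's allele should appear in roughly
half the reads, a homozygote's in nearly all; 15/85 leaves three binomial
standard deviations of slack at the minimum depth of 8 reads for typical
depths, while catching most collapsed-repeat and allele-dropout artifacts
as incorrect cells.

## Locus filtering

Loci are retained when both

* **completeness**: the fraction of samples with a non-missing *correct*
  cell is strictly greater than `completeness` (0.9), and
* **correctness**: the fraction of non-missing cells that are correct is
  strictly greater than `correctness` (0.9).

Both comparisons are strict (`>`), matching the ">90%" convention of the
workflow the defaults come from. Incorrect cells inside retained loci are
set missing rather than reinterpreted. Scoring completeness on the cells
that actually survive (the correct ones) makes the filter *idempotent* —
filtering its own output changes nothing — and monotone in both
thresholds; scoring it on all non-missing cells would not be idempotent,
because masking incorrect cells would lower completeness on a second pass.

The same completeness logic applies one stage earlier at read level:
frames are pre-selected when more than `completeness` of samples have at
least `min_depth` (8) spanning reads, so that loci represent the whole
cohort rather than the deepest samples.

## Relatedness: Jaccard Inverse Distance

For samples $a$ and $b$, restrict to loci where both have a non-missing,
correct cell (pairwise-complete handling, maximizing data use per pair).
Each sample's item set is its (locus, haplotype) pairs with dosage ≥ 1;
dosage magnitude (1 vs 2) deliberately does not weight the computation —
the distance is about shared alleles, not shared genotypes. Then

$$\mathrm{JID}(a,b) = 1 - \frac{|A \cap B|}{|A \cup B|}.$$

The Jaccard ratio is computed globally over all locus–haplotype items
rather than averaged per locus: items from different loci are disjoint, so
the global ratio is the union-weighted aggregate
$\sum_\ell |A_\ell \cap B_\ell| / \sum_\ell |A_\ell \cup B_\ell|$, which
keeps low-diversity loci from dominating an unweighted per-locus average.
JID is a semimetric on call profiles: symmetric, zero on identical
profiles, in $[0,1]$, but not guaranteed to satisfy the triangle
inequality.

Bootstrap replicates resample **loci** with replacement to the original
locus count and recompute the full matrix; marker-sampling variance is
what node support on the tree should reflect, so samples are never
resampled. The per-locus decomposition above makes each replicate a pair
of inner products, so hundreds of replicates are cheap.

## Trees

Neighbor-Joining (Saitou–Nei) is run on the JID matrix via `ape::nj` — the
standard implementation in R phylogenetics. Negative branch lengths, which
NJ can produce on non-additive distance matrices, are clamped to zero with
a message stating the total amount clamped. Node support is the percentage
of replicate trees containing the same leaf bipartition (topology only;
branch lengths ignored), computed over the locus-bootstrap JID matrices.

## SNP-level estimators

Bi-allelic SNPs are hard-filtered on the standard site annotations
(fail if QD < 2.0, FS > 60.0, SOR > 3.0, MQ < 40.0 or MQRankSum < −8.0).
A record missing an annotation passes that annotation's test — the
standard convention for hard filters, since rank-sum annotations are
undefined for sites without heterozygotes. Multi-allelic and indel records
are dropped on ingest with a reported count. No LD or minor-allele
frequency filtering is applied anywhere, so that sample-unique alleles
(including singletons: one heterozygote on an otherwise fixed background)
remain visible.

Per population and locus with $n \ge 2$ genotyped diploids, allele
frequency $p$, and observed heterozygosity $H_o$:

$$H_s = \frac{n}{n-1}\left(1 - \sum_a p_a^2 - \frac{H_o}{2n}\right),
\qquad F_{IS} = 1 - H_o/H_s,$$

the Nei–Chesser small-sample correction. Loci monomorphic within a
population ($H_s = 0$, $F_{IS}$ undefined) are skipped for that
population; reported values are unweighted means over the remaining loci.

Pairwise $F_{ST}$ follows Nei's corrected two-population estimator: per
locus, with $\tilde n$ the harmonic mean sample size, $H_o$ and
$\sum_a p_{ka}^2$ averaged over the two populations and $\bar p$ the
unweighted mean frequency,

$$H_t = 1 - \sum_a \bar p_a^2 + \frac{H_s}{2\tilde n} -
\frac{H_o}{4\tilde n}, \qquad
F_{ST} = \frac{\sum_\ell H_t - \sum_\ell H_s}{\sum_\ell H_t},$$

a ratio of sums (averages) over loci, not an average of per-locus ratios —
the standard multi-locus behaviour, which keeps near-monomorphic loci from
injecting unstable ratios.

Windowed nucleotide diversity uses the unbiased per-site estimator
$\pi_{site} = 2 c_{ref} c_{alt} / (n(n-1))$ on non-missing allele counts,
summed in non-overlapping windows (default 50 kb) anchored at position 0
of each contig and divided by the window length. Windows without variant
sites are omitted, and the reported population value is the unweighted
mean over reported windows.

PCA of the 0/1/2 genotype matrix mean-imputes missing entries per locus
and centers columns without unit-variance scaling. Imputation to the locus
mean is neutral (imputed entries contribute nothing to covariance), and
scaling is omitted because 0/1/2 genotypes are already on one scale;
low-missingness panels are insensitive to either choice.

## The synthetic cohort generator

The generator emulates the study design the pipeline targets: a diploid
cohort from two diverged species, each with nested subpopulations, shotgun
sequenced and aligned to one reference. Defaults (chosen once, as the
package's study conditions at desk scale):

| parameter | default | rationale |
|---|---|---|
| contigs × length | 2 × 50 kb | two contigs exercise per-contig logic; 100 kb keeps a full run near a minute |
| samples | 2 species × 2 subpops × 5 diploids | smallest layout with all three comparison levels (within-subpop, between-subpop, between-species) |
| `snp_density` | 0.02 | ~0.8 SNPs per 40-bp frame, giving a realistic mix of monomorphic, single-SNP and multi-SNP loci |
| `species_divergence` | 0.3 | a third of polymorphic sites fixed between species: clear but not caricatural separation |
| `subpop_drift` | 0.15 | per-site frequency perturbation giving subpopulation F_ST ≈ 0.05 — clearly differentiated neighbouring subpopulations, the regime the JID layering is about; 0.05 would make subpopulations nearly indistinguishable |
| `admixture_fraction` | 0 | admixture is an option, not a default condition |
| `read_length` | 150 | standard short-read length |
| `mean_depth` | 30× | middle of the 10–100× WGS range; ~22 reads span a 40-bp frame |
| `error_rate` | 0.002 | typical Illumina substitution load; exercises the 10% noise floor |
| `fail_annotation_rate` | 0.1 | truth-VCF sites drawn from a fail-like annotation mixture so the hard-filter stage sees both outcomes |

Sites are polymorphic independently with probability `snp_density`. A
divergent site (probability `species_divergence`) has alternative-allele
frequency 1 in species A and 0 in species B; a shared site draws one
ancestral frequency uniformly on [0.1, 0.9] for both species (bounded away
from 0/1 so "shared" sites are genuinely polymorphic). Subpopulation
frequencies add Normal(0, `subpop_drift`) noise, clamped to [0, 1].
Individuals draw two phased alleles as independent Bernoulli trials; each
simulated read copies one whole chromosome copy, so reads carry true
phase. Reads are emitted as already-aligned, coordinate-sorted records
with exact positions, full-match CIGARs and a single mapping quality —
single-end, since haplotyping only ever uses single frame-spanning reads.

**What the generator does not emulate**, and what passing tests therefore
do not show about real data: alignment and reference bias (reads are
placed, not mapped), repeats and paralogy (random reference), indels and
structural variation, base-quality structure and error-rate heterogeneity,
PCR duplicates, paired-end insert geometry, linkage beyond the frame scale
(sites are independent given the frequencies), and chloroplast/organellar
genomes. Results on real WGS data depend on upstream trimming, mapping and
variant-calling quality in ways the simulator cannot probe.

All randomness flows from one integer seed; each stage derives a fixed
child seed, so identical configurations give byte-identical FASTA/SAM/VCF
outputs.

## The naive pileup caller

On synthetic data the pipeline needs genotypes but not a production
variant caller, so `naive_pileup_caller()` implements transparent
majority-composition calling: a site is emitted when some sample shows two
alleles each at ≥ 20% of its pileup; per sample, alleles ≥ 20% determine
hom/het calls, depth < 8 is missing, and a third passing allele marks the
genotype missing. Its annotations are pass-like constants. On real data a
haplotype-based caller's VCF is supplied instead via
`pipeline_config(vcf = ...)`. The caller is validated against simulation
truth (exact concordance on error-free data), not against other callers.

## Numerical choices and degenerate inputs

* All threshold comparisons in the filters are strict (`>`, or `<` for
  fail conditions), matching their ">90%"-style definitions; boundary
  values never flip outcomes.
* Dosage calling is scale-invariant in the read counts (frequencies only).
* An empty dosage matrix, a depth matrix with zero samples, fewer than 3
  samples for NJ, fewer than 2 for PCA, an asymmetric or NA-containing
  distance matrix, unknown samples, and SNP positions outside their frame
  all raise immediate errors naming the offence.
* A pair of samples sharing no loci has missing JID; a sample with no
  correct cells has missing (not zero) heterozygous-locus fraction.
* NJ Q-criterion ties are resolved by `ape::nj`'s deterministic scan
  order; relabeling leaves permutes the topology without changing it.
* Bootstrap replicate matrices are deterministic given the seed, and a
  single-locus table bootstraps to identical replicates.

## Problem sizes used by the test suite

The suite validates estimators against brute-force oracles on small random
instances (≤ 5 samples × 20 loci for JID enumeration, ≤ 5 loci × 10
samples for the heterozygosity formulas, ≤ 12 taxa for NJ additivity), and
runs two simulated cohorts end to end: the default conditions above
(20 samples × 100 kb, 200 bootstrap replicates) for structure recovery,
and an error-free 12-sample × 100 kb cohort at 70× for exact recovery.
70× rather than 30× for the exact-recovery cohort is a property of the
dosage bounds, not an implementation convenience: at ~22 spanning reads a
true heterozygote's minor haplotype falls below the 15% bound by binomial
sampling alone in roughly 4 cells per 10 000, so exact cohort-wide
recovery is only a theorem at depths where that probability vanishes
(~10⁻⁷ per cell at 70×).

## Known limitations

* Diploid only: the dosage bounds and correctness rule are written for
  ploidy 2; polyploid interval sets are not implemented.
* Haplotypes are strictly frame-local; the method gains no information
  from read pairs or from SNPs in adjacent frames.
* JID has no explicit model of allele-sharing by descent; it is a
  similarity coefficient, not a kinship estimator.
* F_ST values between populations of 2–5 individuals are noisy; the
  estimators carry the small-sample corrections but cannot manufacture
  power.
* The hard-filter stage trusts the annotations it is given; it recomputes
  nothing from reads.
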