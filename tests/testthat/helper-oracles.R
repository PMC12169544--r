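# Independent oracles used to freeze expected values. Each is written as a
# direct, brute-force evaluation of the definition it checks, sharing no code
# with the package implementation.

# Closed-form expected fraction of truth-genotype differences between one
# species-A and one species-B individual, under zero drift and admixture:
# divergent sites always differ (genotypes 2 vs 0); shared sites draw both
# genotypes Bin(2, p) with p ~ U(0.1, 0.9).
oracle_expected_geno_diff <- function(species_divergence) {
  match_prob <- function(p) {
    q <- 1 - p
    (p^2)^2 + (2 * p * q)^2 + (q^2)^2
  }
  shared <- stats::integrate(function(p) 1 - match_prob(p), 0.1, 0.9)$value / 0.8
  species_divergence + (1 - species_divergence) * shared
}

# Brute-force per-position pileup oracle for spanning-read counting. Reads
# are rows with pos (1-based), cigar, mapq; the frame is 0-based half-open.
oracle_spanning_depth <- function(reads, frame_start0, frame_end0, min_mapq) {
  frame_pos <- (frame_start0 + 1L):frame_end0
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$mapq[i] < min_mapq) next
    ops <- oracle_parse_cigar(reads$cigar[i])
    ref <- reads$pos[i]
    covered <- integer(0)
    indel_hit <- FALSE
    for (k in seq_len(nrow(ops))) {
      w <- ops$len[k]
      op <- ops$op[k]
      if (op %in% c("M", "=", "X")) {
        covered <- c(covered, ref:(ref + w - 1L))
        ref <- ref + w
      } else if (op %in% c("D", "N")) {
        if (ref <= frame_end0 && ref + w - 1L >= frame_start0 + 1L) {
          indel_hit <- TRUE
        }
        ref <- ref + w
      } else if (op == "I") {
        if (ref >= frame_start0 + 1L && ref <= frame_end0) indel_hit <- TRUE
      }
      # S/H consume no reference
    }
    if (!indel_hit && all(frame_pos %in% covered)) n <- n + 1L
  }
  n
}

oracle_parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]", "", m)),
             op = sub("[0-9]+", "", m), stringsAsFactors = FALSE)
}

# Exhaustive set-enumeration Jaccard Inverse Distance between two samples of
# a dosage matrix, looping loci and building explicit item sets.
oracle_jid <- function(dm, a, b) {
  items <- function(s, loci) {
    out <- character(0)
    for (l in loci) {
      rows <- dm$calls[dm$calls$locus_id == l & dm$calls$sample == s &
                         !is.na(dm$calls$dosage) & dm$calls$dosage >= 1L, ]
      out <- c(out, paste(l, rows$haplotype))
    }
    unique(out)
  }
  correct_loci <- function(s) {
    cc <- dm$cells[dm$cells$sample == s & !is.na(dm$cells$dosage_sum) &
                     dm$cells$dosage_sum == dm$ploidy, ]
    cc$locus_id
  }
  shared <- intersect(correct_loci(a), correct_loci(b))
  if (!length(shared)) return(NA_real_)
  A <- items(a, shared); B <- items(b, shared)
  1 - length(intersect(A, B)) / length(union(A, B))
}

# Direct per-locus evaluation of the Nei-Chesser single-population formulas.
oracle_het_stats_pop <- function(g) {
  Ho_l <- Hs_l <- Fis_l <- numeric(0)
  for (i in seq_len(nrow(g))) {
    x <- g[i, ][!is.na(g[i, ])]
    n <- length(x)
    if (n < 2) next
    p <- sum(x) / (2 * n)
    if (p == 0 || p == 1) next
    Ho <- mean(x == 1)
    Hs <- (n / (n - 1)) * (1 - p^2 - (1 - p)^2 - Ho / (2 * n))
    Ho_l <- c(Ho_l, Ho); Hs_l <- c(Hs_l, Hs)
    if (Hs > 0) Fis_l <- c(Fis_l, 1 - Ho / Hs)
  }
  c(Ho = mean(Ho_l), Hs = mean(Hs_l), Fis = mean(Fis_l))
}

# Direct windowed nucleotide diversity over one contig.
oracle_windowed_pi <- function(pos, gt, window_size) {
  win <- (pos - 1) %/% window_size
  vals <- c()
  for (w in sort(unique(win))) {
    tot <- 0
    for (i in which(win == w)) {
      x <- gt[i, ][!is.na(gt[i, ])]
      n <- 2 * length(x)
      if (n < 2) next
      ca <- sum(x); cr <- n - ca
      tot <- tot + 2 * ca * cr / (n * (n - 1))
    }
    vals <- c(vals, tot / window_size)
  }
  vals
}

# Random small dosage matrix for enumeration checks: per (locus, sample)
# cell: missing, a correct het/hom call, or an incorrect cell (dosage sum
# != ploidy) that must be excluded from JID.
random_dosage_matrix <- function(n_samples, n_loci, p_missing = 0.2,
                                 p_incorrect = 0.1) {
  samples <- sprintf("S%02d", seq_len(n_samples))
  loci <- sprintf("L%02d", seq_len(n_loci))
  haps <- c("AA", "AC", "CA", "CC")
  calls <- cells <- list()
  for (l in loci) for (s in samples) {
    u <- stats::runif(1)
    if (u < p_missing) next
    if (u < p_missing + p_incorrect) {
      h <- sample(haps, 3)
      calls[[length(calls) + 1]] <- data.frame(
        locus_id = l, sample = s, haplotype = h, dosage = 1L)
      cells[[length(cells) + 1]] <- data.frame(
        locus_id = l, sample = s, n_reads = 20L, dosage_sum = 3L)
    } else {
      h <- sample(haps, 2)
      if (stats::runif(1) < 0.5) {
        calls[[length(calls) + 1]] <- data.frame(
          locus_id = l, sample = s, haplotype = h, dosage = c(1L, 1L))
      } else {
        calls[[length(calls) + 1]] <- data.frame(
          locus_id = l, sample = s, haplotype = h[1], dosage = 2L)
      }
      cells[[length(cells) + 1]] <- data.frame(
        locus_id = l, sample = s, n_reads = 20L, dosage_sum = 2L)
    }
  }
  structure(list(calls = do.call(rbind, calls), cells = do.call(rbind, cells),
                 samples = samples, loci = loci, ploidy = 2L),
            class = "dosage_matrix")
}

# Hand-assemble a dosage_matrix from a list: dm_cells[[locus]][[sample]] is
# a named dosage vector, or NULL for missing.
make_dosage_matrix <- function(dm_cells, samples, ploidy = 2L) {
  calls <- cells <- list()
  for (l in names(dm_cells)) for (s in names(dm_cells[[l]])) {
    d <- dm_cells[[l]][[s]]
    if (is.null(d)) next
    cells[[length(cells) + 1]] <- data.frame(
      locus_id = l, sample = s, n_reads = NA_integer_,
      dosage_sum = as.integer(sum(d)))
    keep <- d >= 1L
    if (any(keep)) {
      calls[[length(calls) + 1]] <- data.frame(
        locus_id = l, sample = s, haplotype = names(d)[keep],
        dosage = as.integer(d[keep]))
    }
  }
  structure(list(calls = do.call(rbind, calls), cells = do.call(rbind, cells),
                 samples = samples, loci = names(dm_cells),
                 ploidy = as.integer(ploidy)),
            class = "dosage_matrix")
}
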