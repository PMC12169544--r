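#' Observed/expected heterozygosity and FIS per population
#'
#' Per population and bi-allelic locus with at least two genotyped samples:
#' Ho is the fraction of heterozygotes among non-missing genotypes and Hs the
#' sample-size-corrected gene diversity
#' \deqn{Hs = n/(n-1) (1 - \sum_a p_a^2 - Ho/(2n))}
#' (Nei & Chesser correction, n = genotyped sample count). FIS = 1 - Ho/Hs.
#' Population values are means over loci polymorphic within the population
#' (monomorphic loci, where Hs = 0 and FIS is undefined, are skipped).
#'
#' @param gt Genotype matrix coded 0/1/2/NA (loci x samples).
#' @param assignment Named character vector: sample -> population label.
#' @return data.frame with one row per population: \code{pop, n_samples,
#'   n_loci, Ho, Hs, Fis}.
#' @export
het_stats <- function(gt, assignment) {
  pops <- split(names(assignment), unname(assignment))
  out <- lapply(names(pops), function(p) {
    smp <- intersect(pops[[p]], colnames(gt))
    stats_one_pop(gt[, smp, drop = FALSE], p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

stats_one_pop <- function(g, pop) {
  n <- rowSums(!is.na(g))
  het <- rowSums(g == 1L, na.rm = TRUE)
  alt <- rowSums(g, na.rm = TRUE)
  p <- alt / (2 * n)
  Ho <- het / n
  Hs <- (n / (n - 1)) * (1 - (p^2 + (1 - p)^2) - Ho / (2 * n))
  use <- n >= 2L & p > 0 & p < 1
  Hs[Hs < 0 & use] <- 0  # guard tiny negative rounding
  Fis <- 1 - Ho / Hs
  data.frame(pop = pop, n_samples = ncol(g), n_loci = sum(use),
             Ho = mean(Ho[use]), Hs = mean(Hs[use]),
             Fis = mean(Fis[use & Hs > 0]), stringsAsFactors = FALSE)
}

#' Windowed nucleotide diversity
#'
#' Per site, \eqn{\pi = 2 c_{ref} c_{alt} / (n (n-1))} with allele counts
#' over non-missing genotypes and n their total; windows are
#' \code{window_size}-bp non-overlapping bins anchored at position 0 of each
#' contig; a window's value is the sum of its site values divided by
#' \code{window_size}. Windows without variant sites are omitted and the
#' mean is unweighted over reported windows.
#'
#' @param x A \code{\link{snp_set}}, or a data.frame with \code{contig},
#'   \code{pos} plus a genotype matrix passed as \code{gt}.
#' @param window_size Window length in bp (default 50000).
#' @param samples Optional subset of samples (e.g. one population).
#' @param gt Genotype matrix when \code{x} is a plain site table.
#' @return List: \code{windows} (data.frame \code{contig, start, end, n_snps,
#'   pi}) and \code{mean_pi}.
#' @export
windowed_pi <- function(x, window_size = 50000L, samples = NULL, gt = NULL) {
  if (window_size <= 0) stop("window_size must be positive", call. = FALSE)
  if (inherits(x, "snp_set")) {
    sites <- x$sites; gt <- x$gt
  } else {
    sites <- x
    if (is.null(gt)) stop("gt matrix required", call. = FALSE)
  }
  if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
  ngeno <- rowSums(!is.na(gt))
  c_alt <- rowSums(gt, na.rm = TRUE)
  n <- 2 * ngeno
  c_ref <- n - c_alt
  pi_site <- ifelse(n >= 2, 2 * c_ref * c_alt / (n * (n - 1)), NA_real_)
  use <- !is.na(pi_site)
  win <- (sites$pos[use] - 1L) %/% window_size
  key <- paste(sites$contig[use], win, sep = "\r")
  agg <- tapply(pi_site[use], key, sum)
  cnt <- tapply(pi_site[use], key, length)
  parts <- do.call(rbind, strsplit(names(agg), "\r"))
  windows <- data.frame(contig = parts[, 1],
                        start = as.integer(parts[, 2]) * window_size,
                        stringsAsFactors = FALSE)
  windows$end <- windows$start + window_size
  windows$n_snps <- as.integer(cnt)
  windows$pi <- as.numeric(agg) / window_size
  windows <- windows[order(windows$contig, windows$start), , drop = FALSE]
  rownames(windows) <- NULL
  list(windows = windows,
       mean_pi = if (nrow(windows)) mean(windows$pi) else NA_real_)
}

#' Pairwise Nei FST between populations
#'
#' For each population pair, the Nei (1987) multi-locus estimator with
#' Nei-Chesser sample-size corrections: per locus (both populations with at
#' least two genotyped samples), with harmonic-mean sample size
#' \eqn{\tilde n}, mean within-population homozygosity and allele
#' frequencies,
#' \deqn{Hs = \tilde n/(\tilde n - 1) (1 - mean_k \sum_a p_{ka}^2 - Ho/(2\tilde n))}
#' \deqn{Ht = 1 - \sum_a \bar p_a^2 + Hs/(2\tilde n) - Ho/(4\tilde n)}
#' and FST = (sum Ht - sum Hs)/(sum Ht) over loci (ratio of averages).
#'
#' @param gt Genotype matrix coded 0/1/2/NA (loci x samples).
#' @param assignment Named character vector: sample -> population.
#' @return Symmetric numeric matrix of pairwise FST (diagonal 0); a pair
#'   involving a population with fewer than 2 samples is NA.
#' @export
pairwise_neifst <- function(gt, assignment) {
  pops <- sort(unique(unname(assignment)))
  res <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    res[i, j] <- res[j, i] <- nei_fst_pair(gt, assignment, pops[i], pops[j])
  }
  res
}

nei_fst_pair <- function(gt, assignment, pop1, pop2) {
  g1 <- gt[, names(assignment)[assignment == pop1], drop = FALSE]
  g2 <- gt[, names(assignment)[assignment == pop2], drop = FALSE]
  if (ncol(g1) < 2L || ncol(g2) < 2L) return(NA_real_)
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  use <- n1 >= 2L & n2 >= 2L
  if (!any(use)) return(NA_real_)
  p1 <- rowSums(g1, na.rm = TRUE)[use] / (2 * n1[use])
  p2 <- rowSums(g2, na.rm = TRUE)[use] / (2 * n2[use])
  ho1 <- rowSums(g1 == 1L, na.rm = TRUE)[use] / n1[use]
  ho2 <- rowSums(g2 == 1L, na.rm = TRUE)[use] / n2[use]
  nt <- 2 / (1 / n1[use] + 1 / n2[use])
  Ho <- (ho1 + ho2) / 2
  mean_sum_p2 <- ((p1^2 + (1 - p1)^2) + (p2^2 + (1 - p2)^2)) / 2
  Hs <- (nt / (nt - 1)) * (1 - mean_sum_p2 - Ho / (2 * nt))
  pbar <- (p1 + p2) / 2
  Ht <- 1 - (pbar^2 + (1 - pbar)^2) + Hs / (2 * nt) - Ho / (4 * nt)
  ok <- Ht > 0
  if (!any(ok)) return(NA_real_)
  (sum(Ht[ok]) - sum(Hs[ok])) / sum(Ht[ok])
}

#' PCA of a genotype matrix
#'
#' Missing genotypes are mean-imputed per locus; columns (loci) are centered
#' and by default not scaled; the decomposition is the eigendecomposition of
#' the sample covariance (via \code{prcomp}).
#'
#' @param gt Genotype matrix coded 0/1/2/NA (loci x samples).
#' @param center Center loci (default TRUE).
#' @param scale Unit-variance scale loci (default FALSE).
#' @return List: \code{scores} (samples x PCs), \code{explained}
#'   (non-increasing variance fractions summing to <= 1), \code{sdev}.
#' @export
genotype_pca <- function(gt, center = TRUE, scale = FALSE) {
  if (ncol(gt) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  X <- t(gt)  # samples x loci
  mu <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- mu[nas[, 2]]
  keep <- apply(X, 2L, function(v) stats::var(v) > 0)
  if (scale) X <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(X, center = center, scale. = scale)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained = expl, sdev = pc$sdev)
}
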