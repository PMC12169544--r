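test_that("heterozygosity statistics match the corrected formulas", {
  # 10 diploids all heterozygous: Ho = 1, p = 0.5,
  # Hs = (10/9)(1 - 0.5 - 0.05) = 0.5, FIS = -1
  g <- matrix(1L, nrow = 1, ncol = 10,
              dimnames = list("c1:1", paste0("s", 1:10)))
  r <- het_stats(g, stats::setNames(rep("P", 10), paste0("s", 1:10)))
  expect_equal(r$Ho, 1)
  expect_equal(r$Hs, 0.5)
  expect_equal(r$Fis, -1)

  # monomorphic loci are skipped; Ho = Hs gives FIS = 0
  g2 <- rbind(rep(0L, 10), c(rep(1L, 5), 2L, 2L, 0L, 0L, 0L))
  dimnames(g2) <- list(c("c1:1", "c1:2"), paste0("s", 1:10))
  r2 <- het_stats(g2, stats::setNames(rep("P", 10), paste0("s", 1:10)))
  expect_equal(r2$n_loci, 1L)
  oc <- oracle_het_stats_pop(g2)
  expect_equal(r2$Ho, unname(oc["Ho"]))
  expect_equal(r2$Hs, unname(oc["Hs"]))
  expect_equal(r2$Fis, unname(oc["Fis"]))
})

test_that("heterozygosity statistics equal brute-force evaluation on random panels", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:10, 1); L <- sample(1:5, 1)
    g <- matrix(sample(c(0L, 1L, 2L, NA), n * L, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), nrow = L)
    dimnames(g) <- list(paste0("c1:", seq_len(L)), paste0("s", seq_len(n)))
    oc <- oracle_het_stats_pop(g)
    if (is.nan(oc["Ho"])) next
    r <- het_stats(g, stats::setNames(rep("P", n), colnames(g)))
    expect_equal(r$Ho, unname(oc["Ho"]), tolerance = 1e-12)
    expect_equal(r$Hs, unname(oc["Hs"]), tolerance = 1e-12)
    if (!is.nan(oc["Fis"])) {
      expect_equal(r$Fis, unname(oc["Fis"]), tolerance = 1e-12)
    }
  }
})

test_that("windowed nucleotide diversity matches hand arithmetic and the oracle", {
  # one site, 10 chromosomes, 4 alt / 6 ref in a 50 kb window
  g <- matrix(c(2L, 2L, 0L, 0L, 0L), nrow = 1,
              dimnames = list(NULL, paste0("s", 1:5)))
  sites <- data.frame(contig = "c1", pos = 123L)
  r <- windowed_pi(sites, 50000, gt = g)
  expect_equal(r$windows$pi, ((2 * 4 * 6) / 90) / 50000, tolerance = 1e-12)
  expect_equal(r$mean_pi, 1.0666667e-05, tolerance = 1e-6)

  # all-alt site contributes zero; empty windows are omitted
  g2 <- rbind(g, rep(2L, 5))
  sites2 <- data.frame(contig = "c1", pos = c(123L, 60001L))
  r2 <- windowed_pi(sites2, 50000, gt = g2)
  expect_equal(nrow(r2$windows), 2L)
  expect_equal(r2$windows$pi[2], 0)

  expect_error(windowed_pi(sites, 0, gt = g), "window_size")

  # ref/alt label swap invariance + random oracle equivalence
  set.seed(17)
  for (i in 1:10) {
    L <- sample(3:25, 1)
    gt <- matrix(sample(c(0L, 1L, 2L, NA), L * 8, replace = TRUE), nrow = L)
    colnames(gt) <- paste0("s", 1:8)
    pos <- sort(sample(1:120000, L))
    st <- data.frame(contig = "c1", pos = pos)
    a <- windowed_pi(st, 50000, gt = gt)
    b <- windowed_pi(st, 50000, gt = 2L - gt)
    expect_equal(a$windows$pi, b$windows$pi, tolerance = 1e-12)
    expect_equal(a$windows$pi, oracle_windowed_pi(pos, gt, 50000),
                 tolerance = 1e-12)
  }
})

test_that("pairwise Nei FST behaves at the degenerate extremes", {
  samples <- paste0("s", 1:20)
  assign <- stats::setNames(rep(c("P1", "P2"), each = 10), samples)
  # identical fully heterozygous populations: FST = 0 exactly
  g_het <- matrix(1L, nrow = 5, ncol = 20, dimnames = list(NULL, samples))
  expect_equal(pairwise_neifst(g_het, assign)["P1", "P2"], 0)
  # populations fixed for different alleles: FST -> 1
  g_fix <- matrix(rep(c(0L, 2L), each = 10), nrow = 5, ncol = 20, byrow = TRUE,
                  dimnames = list(NULL, samples))
  expect_equal(pairwise_neifst(g_fix, assign)["P1", "P2"], 1)
  # matrix shape
  m <- pairwise_neifst(g_fix, assign)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(P1 = 0, P2 = 0))
  # a population of one sample yields NA
  assign1 <- stats::setNames(c(rep("P1", 19), "P2"), samples)
  expect_true(is.na(pairwise_neifst(g_fix, assign1)["P1", "P2"]))
})

test_that("label permutation on panmictic genotypes gives near-zero FST", {
  set.seed(23)
  n <- 40; L <- 400
  p <- runif(L, 0.2, 0.8)
  g <- matrix(rbinom(n * L, 2, rep(p, n)), nrow = L)
  colnames(g) <- paste0("s", 1:n)
  vals <- replicate(20, {
    lab <- sample(rep(c("P1", "P2"), each = n / 2))
    pairwise_neifst(g, stats::setNames(lab, colnames(g)))["P1", "P2"]
  })
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("genotype PCA matches a dense eigendecomposition oracle", {
  set.seed(29)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 200 * 12, replace = TRUE,
                     prob = c(0.4, 0.3, 0.25, 0.05)), nrow = 200)
  colnames(g) <- paste0("s", 1:12)
  r <- genotype_pca(g)
  # oracle: impute to locus mean, center, eigenvalues of sample covariance
  X <- t(g)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(r$explained[seq_along(ev)], ev / sum(ev), tolerance = 1e-8)
  expect_true(all(diff(r$explained) <= 1e-12))
  expect_lte(sum(r$explained), 1 + 1e-8)
})

test_that("PCA separates duplicated clusters degenerately", {
  g <- cbind(matrix(0L, 60, 4), matrix(2L, 60, 4))
  colnames(g) <- paste0("s", 1:8)
  r <- genotype_pca(g)
  pc1 <- r$scores[, 1]
  expect_equal(stats::sd(pc1[1:4]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(pc1[5:8]), 0, tolerance = 1e-9)
  expect_gt(abs(mean(pc1[1:4]) - mean(pc1[5:8])), 1)
  # duplicated sample gets identical coordinates
  g2 <- cbind(g, s9 = g[, 1])
  r2 <- genotype_pca(g2)
  expect_equal(unname(r2$scores["s9", ]), unname(r2$scores["s1", ]),
               tolerance = 1e-9)
  expect_error(genotype_pca(g[, 1, drop = FALSE]), "2 samples")
})
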