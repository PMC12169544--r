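test_that("haplotype extraction phases SNPs within a frame from single reads", {
  # frame c1:[100,140); SNPs at 1-based 111 and 131 (offsets 10 and 30)
  ref150 <- strrep("A", 150)
  mk <- function(b1, b2) {
    s <- ref150
    substr(s, 111 - 90, 111 - 90) <- b1   # reads start at pos 91
    substr(s, 131 - 90, 131 - 90) <- b2
    s
  }
  reads <- data.frame(
    qname = sprintf("r%02d", 1:23), rname = "c1", pos = 91L, mapq = 60L,
    cigar = "150M",
    seq = c(rep(mk("A", "C"), 10), rep(mk("G", "T"), 10),
            mk("A", "C"), mk("A", "C"), mk("A", "C")),
    stringsAsFactors = FALSE)
  # one partial read (spans only first SNP), one deletion inside frame,
  # one low mapq: all excluded
  reads$pos[21] <- 91L;  reads$cigar[21] <- "30M"; reads$seq[21] <- substr(mk("A", "C"), 1, 30)
  reads$cigar[22] <- "25M2D123M"; reads$seq[22] <- substr(mk("A", "C"), 1, 148)
  reads$mapq[23] <- 10L
  sam <- write_test_sam(reads, c(c1 = 400L))
  frame <- list(contig = "c1", start = 100L, end = 140L)
  h <- extract_haplotypes(frame, c(111L, 131L), sam, min_mapq = 30)
  expect_equal(h[order(names(h))], c(AC = 10L, GT = 10L))

  expect_error(extract_haplotypes(frame, c(99L, 131L), sam), "inside the frame")
  # zero-SNP frame: single monomorphic haplotype counting the 20 spanning
  # reads (partial, deletion and low-mapq reads remain excluded)
  h0 <- extract_haplotypes(frame, integer(0), sam, min_mapq = 30)
  expect_equal(h0, c("." = 20L))
})

test_that("dosage calling follows the frequency interval bounds", {
  expect_equal(call_dosage(c(AC = 10, GT = 10)), c(AC = 1L, GT = 1L))
  expect_equal(call_dosage(c(AC = 19, GT = 1)), c(AC = 2L))
  expect_null(call_dosage(c(AC = 4, GT = 3)))          # total 7 < 8
  # 60/20/20: three dosage-1 alleles, sum 3 -> incorrect cell
  d3 <- call_dosage(c(AA = 12, AC = 4, CC = 4))
  expect_equal(d3[c("AA", "AC", "CC")], c(AA = 1L, AC = 1L, CC = 1L))
  expect_false(correctness_flag(d3))
  expect_true(correctness_flag(call_dosage(c(AC = 10, GT = 10))))
  expect_false(correctness_flag(NULL))
  # noise floor: 10-15% is present-but-absent (dosage 0), no renormalization
  expect_equal(call_dosage(c(A = 88, B = 12)), c(A = 2L))
  expect_error(call_dosage(c(A = -1)), "negative")
  expect_error(call_dosage(c(A = 10), bounds = c(50, 40, 85, 85)), "bounds")
})

test_that("dosage calling is scale-invariant in the counts", {
  set.seed(21)
  for (i in 1:40) {
    k <- sample(1:4, 1)
    counts <- stats::setNames(sample(1:30, k), paste0("h", seq_len(k)))
    if (sum(counts) < 8) counts[1] <- counts[1] + 8L
    for (mult in c(2L, 7L)) {
      expect_identical(call_dosage(counts), call_dosage(counts * mult))
    }
  }
})

test_that("the dosage table matches per-cell call_dosage", {
  set.seed(8)
  rows <- list()
  expected <- list()
  for (l in sprintf("L%02d", 1:12)) for (s in c("s1", "s2", "s3")) {
    k <- sample(1:3, 1)
    counts <- stats::setNames(sample(0:25, k), sample(c("AA", "AG", "GG"), k))
    rows[[paste(l, s)]] <- data.frame(locus_id = l, sample = s,
                                      haplotype = names(counts),
                                      count = unname(counts))
    expected[[paste(l, s)]] <- call_dosage(counts)
  }
  counts_df <- do.call(rbind, rows)
  dm <- dosage_call_table(counts_df)
  for (key in names(expected)) {
    l <- sub(" .*", "", key); s <- sub(".* ", "", key)
    want <- expected[[key]]
    cell <- dm$cells[dm$cells$locus_id == l & dm$cells$sample == s, ]
    if (is.null(want)) {
      expect_equal(nrow(cell), 0L, info = key)
    } else {
      expect_equal(cell$dosage_sum, sum(want), info = key)
      got <- dm$calls[dm$calls$locus_id == l & dm$calls$sample == s, ]
      expect_equal(sort(stats::setNames(got$dosage, got$haplotype)),
                   sort(want[want >= 1L]), info = key)
    }
  }
})

test_that("locus filtering applies strict completeness and correctness", {
  samples <- sprintf("s%02d", 1:38)
  cell_list <- function(n_called, n_correct) {
    cells <- stats::setNames(vector("list", 38), samples)
    for (i in seq_len(n_called)) {
      cells[[i]] <- if (i <= n_correct) c(h1 = 1L, h2 = 1L) else c(h1 = 1L)
    }
    cells
  }
  dm <- make_dosage_matrix(list(
    LA = cell_list(36, 36),   # 36/38 = 0.947 complete, all correct: retained
    LB = cell_list(30, 30),   # 30/38 = 0.789: dropped on completeness
    LC = cell_list(36, 32),   # 32/36 = 0.889 correct: dropped on correctness
    LD = cell_list(0, 0)      # all missing: dropped
  ), samples)
  f <- filter_loci(dm, 0.9, 0.9)
  expect_equal(f$loci, "LA")
  expect_error(filter_loci(make_dosage_matrix(list(), samples)), "empty")
  # incorrect cells inside retained loci become missing
  dm2 <- make_dosage_matrix(list(LA = cell_list(37, 36)), samples)
  f2 <- filter_loci(dm2, 0.9, 0.9)
  expect_equal(nrow(f2$cells), 36L)
  expect_true(all(f2$cells$dosage_sum == 2L))
})

test_that("locus filtering is monotone in both thresholds", {
  set.seed(5)
  dm <- random_dosage_matrix(10, 30)
  for (i in 1:8) {
    c1 <- runif(1, 0, 0.9); c2 <- min(1, c1 + runif(1, 0, 0.4))
    k1 <- runif(1, 0, 0.9); k2 <- min(1, k1 + runif(1, 0, 0.4))
    base <- filter_loci(dm, c1, k1)$loci
    expect_true(all(filter_loci(dm, c2, k1)$loci %in% base))
    expect_true(all(filter_loci(dm, c1, k2)$loci %in% base))
  }
})

test_that("heterozygous-locus fraction counts distinct present haplotypes", {
  dm <- make_dosage_matrix(list(
    L1 = list(s1 = c(h1 = 1L, h2 = 1L), s2 = c(h1 = 2L)),
    L2 = list(s1 = c(h1 = 1L, h3 = 1L), s2 = c(h1 = 2L)),
    L3 = list(s1 = c(h1 = 2L), s2 = c(h1 = 2L)),
    L4 = list(s1 = c(h2 = 2L), s2 = NULL)
  ), c("s1", "s2", "s3"))
  hf <- het_fraction(dm)
  expect_equal(unname(hf["s1"]), 0.5)
  expect_equal(unname(hf["s2"]), 0)
  expect_true(is.na(hf["s3"]))   # no data: missing, not 0
  expect_equal(het_fraction(dm, "s1"), 0.5)
})

test_that("dosage and count tables round-trip through TSV", {
  set.seed(10)
  dm <- random_dosage_matrix(6, 15, p_incorrect = 0)
  p <- tempfile(fileext = ".tsv")
  write_dosage_tsv(dm, p)
  back <- read_dosage_tsv(p)
  ka <- function(d) {
    x <- d$calls[order(d$calls$locus_id, d$calls$sample, d$calls$haplotype), ]
    rownames(x) <- NULL
    x[, c("locus_id", "sample", "haplotype", "dosage")]
  }
  expect_equal(ka(back), ka(dm))
  counts <- data.frame(locus_id = "L1", sample = c("a", "b"),
                       haplotype = c("AC", "GT"), count = c(10L, 12L))
  pc <- tempfile(fileext = ".tsv")
  write_counts_tsv(counts, pc)
  expect_equal(read_counts_tsv(pc), counts)
})

test_that("error-free dosage calls equal truth phased genotypes at retained loci", {
  run <- exact_run()
  truth <- run$dataset$truth
  res <- run$result
  dmf <- res$dosage_filtered
  snp_sites <- res$snps_selected$sites
  frames <- res$selected
  checked <- 0L
  for (l in sample(dmf$loci, min(400, length(dmf$loci)))) {
    f <- frames[frames$locus_id == l, ]
    pos <- sort(snp_sites$pos[snp_sites$contig == f$contig &
                                snp_sites$pos > f$start &
                                snp_sites$pos <= f$end])
    cells <- dmf$cells[dmf$cells$locus_id == l, ]
    for (s in cells$sample) {
      j <- match(s, truth$labels$sample)
      want <- if (length(pos)) {
        truth_frame_dosage(truth, f$contig, pos, j)
      } else c("." = 2L)
      got <- dmf$calls[dmf$calls$locus_id == l & dmf$calls$sample == s, ]
      gotv <- stats::setNames(got$dosage, got$haplotype)
      expect_equal(gotv[order(names(gotv))], want[order(names(want))],
                   info = paste(l, s))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 1000L)
})
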