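#' Jaccard Inverse Distance between two samples
#'
#' Over loci where BOTH samples have a non-missing, correct cell (dosages sum
#' to the ploidy), each sample's item set is its (locus, haplotype) pairs
#' with dosage >= 1; dosage magnitude does not weight the computation.
#' JID = 1 - |A n B| / |A u B|. With no shared loci the value is NA.
#'
#' @param dm A \code{dosage_matrix}.
#' @param a,b Sample names.
#' @return JID in \[0, 1\], or NA.
#' @export
jid <- function(dm, a, b) {
  if (!all(c(a, b) %in% dm$samples)) {
    stop("unknown sample: ", paste(setdiff(c(a, b), dm$samples), collapse = ", "),
         call. = FALSE)
  }
  good <- dm$cells[!is.na(dm$cells$dosage_sum) &
                     dm$cells$dosage_sum == dm$ploidy, , drop = FALSE]
  shared <- intersect(good$locus_id[good$sample == a],
                      good$locus_id[good$sample == b])
  if (!length(shared)) return(NA_real_)
  calls <- dm$calls[!is.na(dm$calls$dosage) & dm$calls$dosage >= 1L &
                      dm$calls$locus_id %in% shared, , drop = FALSE]
  A <- unique(paste(calls$locus_id, calls$haplotype)[calls$sample == a])
  B <- unique(paste(calls$locus_id, calls$haplotype)[calls$sample == b])
  1 - length(intersect(A, B)) / length(union(A, B))
}

# Per-locus pair decomposition used by jid_matrix and bootstrap_jid: since
# items of different loci are distinct, the global Jaccard of a pair equals
# sum_l |A_l n B_l| / sum_l |A_l u B_l| over loci where both have correct
# cells. Returns intersection and union contribution matrices
# (loci x pairs) plus the pair index.
jid_decomposition <- function(dm) {
  samples <- dm$samples
  n <- length(samples)
  loci <- dm$loci
  good <- dm$cells[!is.na(dm$cells$dosage_sum) &
                     dm$cells$dosage_sum == dm$ploidy, , drop = FALSE]
  calls <- dm$calls[!is.na(dm$calls$dosage) & dm$calls$dosage >= 1L, ,
                    drop = FALSE]
  pair_i <- rep(seq_len(n), times = n) ; pair_j <- rep(seq_len(n), each = n)
  keep <- pair_i < pair_j
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  npair <- length(pair_i)
  I <- matrix(0, nrow = length(loci), ncol = npair)
  U <- matrix(0, nrow = length(loci), ncol = npair)
  pair_col <- matrix(0L, n, n)
  pair_col[cbind(pair_i, pair_j)] <- seq_len(npair)
  calls_by_locus <- split(calls[, c("sample", "haplotype")], calls$locus_id)
  good_by_locus <- split(good$sample, good$locus_id)
  for (li in seq_along(loci)) {
    l <- loci[li]
    present <- good_by_locus[[l]]
    if (length(present) < 2L) next
    cl <- calls_by_locus[[l]]
    cl <- cl[cl$sample %in% present, , drop = FALSE]
    P <- table(cl$haplotype, factor(cl$sample, levels = present)) > 0
    M <- crossprod(P)  # pairwise intersections; diagonal = set sizes
    sz <- diag(M)
    idx <- match(present, samples)
    for (x in seq_along(present)) for (y in seq_len(x - 1L)) {
      ii <- min(idx[x], idx[y]); jj <- max(idx[x], idx[y])
      cidx <- pair_col[ii, jj]
      inter <- M[x, y]
      I[li, cidx] <- inter
      U[li, cidx] <- sz[x] + sz[y] - inter
    }
  }
  list(I = I, U = U, pair_i = pair_i, pair_j = pair_j, samples = samples)
}

jid_from_decomposition <- function(dec, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(dec$I))
  inter <- as.numeric(w %*% dec$I)
  uni <- as.numeric(w %*% dec$U)
  val <- ifelse(uni > 0, 1 - inter / uni, NA_real_)
  n <- length(dec$samples)
  M <- matrix(NA_real_, n, n, dimnames = list(dec$samples, dec$samples))
  M[cbind(dec$pair_i, dec$pair_j)] <- val
  M[cbind(dec$pair_j, dec$pair_i)] <- val
  diag(M) <- 0
  M
}

#' Pairwise JID matrix
#'
#' @param dm A \code{dosage_matrix}.
#' @param samples Optional sample order (default \code{dm$samples}).
#' @return Symmetric matrix of JID values with zero diagonal (NA where a pair
#'   shares no loci).
#' @export
jid_matrix <- function(dm, samples = NULL) {
  if (!is.null(samples)) {
    if (!all(samples %in% dm$samples)) stop("unknown sample", call. = FALSE)
    dm$samples <- samples
  }
  jid_from_decomposition(jid_decomposition(dm))
}

#' Locus-bootstrap replicates of the JID matrix
#'
#' Each replicate resamples loci with replacement to the original locus count
#' and recomputes the full pairwise JID matrix. Deterministic given
#' \code{seed}.
#'
#' @param dm A \code{dosage_matrix}.
#' @param n_reps Number of replicates (default 200).
#' @param seed Integer seed.
#' @return List of \code{n_reps} JID matrices.
#' @export
bootstrap_jid <- function(dm, n_reps = 200L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  dec <- jid_decomposition(dm)
  L <- length(dm$loci)
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    jid_from_decomposition(dec, w)
  })
}

#' Write a square distance matrix as TSV
#'
#' @param m Symmetric matrix with sample dimnames.
#' @param path Output path.
#' @export
write_distance_tsv <- function(m, path) {
  utils::write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample
  m
}
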