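#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via \code{ape::nj}. Negative branch lengths are
#' clamped to zero (standard NJ practice); the total clamped amount is
#' reported with a message.
#'
#' @param d Symmetric numeric matrix (e.g. a JID matrix) with sample
#'   dimnames, zero diagonal, no NA; at least 3 samples.
#' @return An unrooted \code{phylo} tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("NJ needs at least 3 samples", call. = FALSE)
  if (any(is.na(d))) stop("distance matrix contains NA", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative NJ branch length(s) totalling ",
            signif(-sum(tr$edge.length[neg]), 3), " to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Annotate bootstrap bipartition support on a tree
#'
#' For each internal edge of the main tree, support is the percentage of
#' replicate NJ trees containing the same leaf bipartition (topology only;
#' branch lengths are ignored). Supports are stored as internal node labels.
#'
#' @param main The main \code{phylo} tree.
#' @param replicates List of replicate trees, or of replicate distance
#'   matrices (each is run through \code{\link{nj_tree}}).
#' @return \code{main} with \code{node.label} set to supports in \[0, 100\].
#' @export
bootstrap_support <- function(main, replicates) {
  trees <- lapply(replicates, function(r) {
    if (inherits(r, "phylo")) r else suppressMessages(nj_tree(r))
  })
  for (t in trees) {
    if (!setequal(t$tip.label, main$tip.label)) {
      stop("replicate tree has a different leaf set", call. = FALSE)
    }
  }
  counts <- ape::prop.clades(main, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- round(100 * counts / length(trees), 1)
  main
}

#' Support of the edge splitting a given tip set
#'
#' Finds the internal edge whose leaf bipartition equals \code{tips} (or its
#' complement) and returns its bootstrap support, or NA when the split is not
#' an edge of the tree.
#'
#' @param tree A \code{phylo} with \code{node.label} supports from
#'   \code{\link{bootstrap_support}}.
#' @param tips Character vector of tip labels on one side of the split.
#' @return Numeric support in \[0, 100\] or NA.
#' @export
edge_support <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  supports <- as.numeric(tree$node.label)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    desc <- tree$tip.label[descendant_tips(tree, node)]
    if (setequal(desc, tips) || setequal(setdiff(tree$tip.label, desc), tips)) {
      return(supports[node - ntip])
    }
  }
  NA_real_
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Newick serialization round-trip
#'
#' @param tree A \code{phylo}.
#' @param path Optional file; when NULL the Newick string is returned.
#' @return \code{write_newick}: the Newick string (invisibly when written to
#'   file). \code{read_newick}: a \code{phylo}.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname write_newick
#' @param text Newick string (alternative to \code{path}).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("provide path or text", call. = FALSE)
    text <- paste(readLines(path), collapse = "")
  }
  if (!nzchar(trimws(text))) stop("empty Newick input", call. = FALSE)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick input", call. = FALSE)
  tr
}
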