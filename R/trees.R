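# Internal: mismatch/compared counts from a raw 0/1/NA matrix.
# Returns NULL when some pair has no mutually scored band.
.diff_counts <- function(x) {
  P <- (x == 1L & !is.na(x)) * 1
  A <- (x == 0L & !is.na(x)) * 1
  Obs <- (!is.na(x)) * 1
  cmp <- tcrossprod(Obs)
  if (any(cmp[upper.tri(cmp)] == 0)) return(NULL)
  d <- tcrossprod(P, A)
  d <- d + t(d)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

.tree_input <- function(d) {
  if (inherits(d, "band_distance")) return(d$diff)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)))
      stop("distance matrix must be symmetric", call. = FALSE)
    return(d)
  }
  stop("expected a band_distance or a symmetric matrix", call. = FALSE)
}

#' UPGMA dendrogram from band differences
#'
#' Average-linkage agglomerative clustering on the raw mismatch counts.
#' Each merge is placed at half the average between-cluster difference, so
#' the tree is rooted and ultrametric: every leaf sits at the same depth and
#' two accessions joined at height *h* differ on average by 2*h* bands.
#'
#' @param d a [pairwise_differences()] result or a symmetric numeric matrix
#'   with accession ids as dimnames.
#' @return an `ape::phylo` tree (rooted, ultrametric), branch lengths in
#'   difference units.
#' @export
upgma_tree <- function(d) {
  dd <- .tree_input(d)
  if (nrow(dd) < 2L) stop("need at least 2 accessions", call. = FALSE)
  ape::as.phylo(stats::hclust(stats::as.dist(dd), method = "average"))
}

#' Neighbor-joining tree from band differences
#'
#' Standard Q-criterion neighbor joining on the raw mismatch counts,
#' yielding an unrooted tree that is exact on additive distances. Estimated
#' negative branch lengths — a known NJ artefact on noisy or non-additive
#' input — are clamped to zero; the number of clamped edges and the total
#' length removed are attached as attributes `n_clamped` and
#' `clamp_deficit` so the run log can report them.
#'
#' @inheritParams upgma_tree
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  dd <- .tree_input(d)
  if (nrow(dd) < 3L) stop("neighbor joining needs at least 3 accessions", call. = FALSE)
  tr <- ape::nj(stats::as.dist(dd))
  neg <- tr$edge.length < 0
  attr(tr, "n_clamped") <- sum(neg)
  attr(tr, "clamp_deficit") <- -sum(tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  tr
}

#' Bootstrap branch support by resampling band columns
#'
#' Builds the point-estimate tree from the full matrix, then resamples the
#' fragment columns with replacement (the classical character bootstrap; the
#' matrix is band-level, so bands are the resampling unit — set
#' `resample = "locus"` to resample whole SSR loci as blocks instead),
#' recomputes pairwise-deletion differences and rebuilds the tree for each
#' replicate. The support of each internal edge of the point-estimate tree
#' is the percentage of replicate trees containing the same leaf
#' bipartition (clade, for the rooted UPGMA case). A replicate whose
#' resampled columns leave some accession pair with no mutually scored band
#' has undefined distances; it is rejected and redrawn, and the number of
#' redraws is recorded.
#'
#' @param m a [band_matrix()].
#' @param method `"upgma"` or `"nj"`.
#' @param n_replicates number of bootstrap replicates (default 500).
#' @param seed optional integer seed; fixing it makes supports reproducible.
#' @param resample `"band"` (default) or `"locus"`; the latter requires the
#'   matrix to carry locus labels.
#' @return the point-estimate `phylo` tree with integer support percentages
#'   as internal node labels (`node.label`), plus attributes `n_replicates`,
#'   `n_redrawn` and `method`.
#' @export
bootstrap_support <- function(m, method = c("upgma", "nj"), n_replicates = 500L,
                              seed = NULL, resample = c("band", "locus")) {
  stopifnot(inherits(m, "band_matrix"))
  method <- match.arg(method)
  resample <- match.arg(resample)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  build <- if (method == "upgma") upgma_tree else nj_tree
  x <- unclass(m)
  d0 <- .diff_counts(x)
  if (is.null(d0))
    stop("some accession pair has no mutually scored band", call. = FALSE)
  point <- build(d0)
  loci <- attr(m, "loci")
  if (resample == "locus" && is.null(loci))
    stop("locus resampling requires a matrix with locus labels", call. = FALSE)
  blocks <- if (resample == "locus") split(seq_len(ncol(x)), loci) else NULL
  n_redrawn <- 0L
  trees <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    repeat {
      cols <- if (resample == "band") {
        sample.int(ncol(x), ncol(x), replace = TRUE)
      } else {
        unlist(blocks[sample.int(length(blocks), length(blocks), replace = TRUE)],
               use.names = FALSE)
      }
      db <- .diff_counts(x[, cols, drop = FALSE])
      if (!is.null(db)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_replicates)
        stop("bootstrap replicates keep producing pairs with no scored bands",
             call. = FALSE)
    }
    trees[[b]] <- build(db)
  }
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(point, trees, rooted = (method == "upgma"))
  counts[is.na(counts)] <- 0L
  point$node.label <- as.character(as.integer(round(100 * counts / n_replicates)))
  attr(point, "n_replicates") <- as.integer(n_replicates)
  attr(point, "n_redrawn") <- n_redrawn
  attr(point, "method") <- method
  point
}

#' Collapse weakly supported branches into polytomies
#'
#' Contracts every internal edge whose child node's bootstrap support is
#' below `min_support`, attaching the children to the grandparent and adding
#' the contracted edge's length to theirs so root-to-leaf path lengths are
#' preserved. Leaves and the supports of the surviving edges are untouched.
#' Nodes with a missing or non-numeric label (e.g. the root) are never
#' contracted.
#'
#' @param tree a `phylo` with support values in `node.label`, e.g. from
#'   [bootstrap_support()].
#' @param min_support minimum support (percent) an internal edge needs to
#'   survive (default 75).
#' @return the collapsed `phylo` tree, possibly with polytomies.
#' @export
collapse_branches <- function(tree, min_support = 75) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label))
    stop("tree has no support labels; run bootstrap_support() first", call. = FALSE)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  repeat {
    supp <- suppressWarnings(as.numeric(tree$node.label))
    ntip <- length(tree$tip.label)
    child <- tree$edge[, 2L]
    internal <- which(child > ntip)
    s <- supp[child[internal] - ntip]
    bad <- internal[!is.na(s) & s < min_support]
    if (!length(bad)) break
    e <- bad[1L]
    parent <- tree$edge[e, 1L]
    cnode <- tree$edge[e, 2L]
    elen <- tree$edge.length[e]
    kids <- tree$edge[, 1L] == cnode
    tree$edge[kids, 1L] <- parent
    tree$edge.length[kids] <- tree$edge.length[kids] + elen
    tree$edge <- tree$edge[-e, , drop = FALSE]
    tree$edge.length <- tree$edge.length[-e]
    tree$node.label <- tree$node.label[-(cnode - ntip)]
    tree$edge[tree$edge > cnode] <- tree$edge[tree$edge > cnode] - 1L
    tree$Nnode <- tree$Nnode - 1L
  }
  tree
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written as-is; bootstrap supports (when present in
#' `node.label`) appear as internal node labels, the convention external
#' tree viewers expect.
#'
#' @param tree a `phylo`.
#' @param path optional file destination; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to `path`).
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Leaf bipartitions of a tree
#'
#' The set of non-trivial splits induced by internal edges, each given as
#' the lexicographically sorted, comma-joined smaller-side tip set (for
#' rooted trees, the clade tip set). Convenient for comparing topologies
#' before and after collapsing.
#'
#' @param tree a `phylo`.
#' @return character vector of canonical split encodings.
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  ntip <- length(labs)
  enc <- vapply(parts, function(p) {
    side <- sort(labs[p])
    other <- sort(labs[-p])
    if (length(side) < length(other) ||
        (length(side) == length(other) && side[1] < other[1]))
      paste(side, collapse = ",")
    else paste(other, collapse = ",")
  }, character(1))
  unique(enc[vapply(parts, length, integer(1)) < ntip])
}
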