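#' @importFrom ape nj as.phylo root is.monophyletic prop.clades prop.part
#'   write.tree read.tree drop.tip
NULL

# integer encoding of an alignment matrix: A,C,G,T -> 1..4, everything else 0
.encodeAlignment <- function(M) {
  E <- matrix(0L, nrow = nrow(M), ncol = ncol(M), dimnames = dimnames(M))
  E[M == "A"] <- 1L; E[M == "C"] <- 2L; E[M == "G"] <- 3L; E[M == "T"] <- 4L
  E
}

#' p-distance between two alignment rows
#'
#' Proportion of differing columns among columns where both rows carry a base
#' in `{A,C,G,T}`; gaps and `N` are excluded from numerator and denominator.
#'
#' @param msa a [PlastomeAlignment-class].
#' @param taxonA,taxonB row names.
#' @return the proportion in `[0, 1]`.
#' @export
pDistance <- function(msa, taxonA, taxonB) {
  M <- alignmentMatrix(msa)
  .check(all(c(taxonA, taxonB) %in% rownames(M)), "unknown taxa")
  E <- .encodeAlignment(M[c(taxonA, taxonB), , drop = FALSE])
  valid <- E[1L, ] > 0L & E[2L, ] > 0L
  .check(sum(valid) > 0L, "no shared non-missing columns between %s and %s",
         taxonA, taxonB)
  sum(E[1L, valid] != E[2L, valid]) / sum(valid)
}

#' Pairwise p-distance matrix of a panel
#'
#' @param msa a [PlastomeAlignment-class].
#' @return list with `d` (symmetric matrix of p-distances, zero diagonal) and
#'   `shared` (per-pair count of compared columns).
#' @export
plastomeDistances <- function(msa) {
  E <- .encodeAlignment(alignmentMatrix(msa))
  ids <- rownames(E)
  k <- length(ids)
  d <- matrix(0, k, k, dimnames = list(ids, ids))
  shared <- matrix(ncol(E), k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      valid <- E[i, ] > 0L & E[j, ] > 0L
      nv <- sum(valid)
      .check(nv > 0L, "no shared non-missing columns between %s and %s",
             ids[i], ids[j])
      dij <- sum(E[i, valid] != E[j, valid]) / nv
      d[i, j] <- d[j, i] <- dij
      shared[i, j] <- shared[j, i] <- nv
    }
  }
  list(d = d, shared = shared)
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]); negative branch
#' lengths are clamped to zero with the deficit moved to the sibling branch.
#' An all-zero distance matrix yields a star tree.
#'
#' @param d symmetric distance matrix (or the list returned by
#'   [plastomeDistances()]).
#' @return an unrooted `phylo` tree.
#' @export
njTree <- function(d) {
  if (is.list(d) && !is.null(d$d)) d <- d$d
  d <- as.matrix(d)
  k <- nrow(d)
  .check(k >= 3L, "need at least three taxa")
  if (all(d == 0)) {
    # star tree: one internal node, zero-length pendant edges
    tr <- list(
      edge = cbind(rep(k + 1L, k), seq_len(k)),
      edge.length = rep(0, k),
      tip.label = rownames(d),
      Nnode = 1L
    )
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  # clamp negative branch lengths; deficit moves to the sibling branch
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sib)) tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
  }
  tr
}

#' Column-bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement (`nReps` replicates,
#' replicate `r` seeded with `seed + r`), rebuilds the NJ tree from the
#' resampled p-distances and reports, on each internal node of the original
#' tree, the percentage of replicates containing that bipartition.
#'
#' Invariant gap-free columns only contribute to p-distance denominators, so
#' replicates are computed from per-column resampling weights applied to the
#' informative columns plus a total weight for the invariant remainder.
#'
#' @param msa a [PlastomeAlignment-class].
#' @param nReps number of bootstrap replicates.
#' @param seed integer seed.
#' @param tree optional original tree (computed from `msa` when `NULL`).
#' @return the original tree with `node.label` set to support percentages.
#' @export
bootstrapSupport <- function(msa, nReps = 100L, seed = 1L, tree = NULL) {
  .check(nReps >= 1L, "nReps must be at least 1")
  E <- .encodeAlignment(alignmentMatrix(msa))
  ids <- rownames(E)
  k <- length(ids)
  nCol <- ncol(E)
  if (is.null(tree)) tree <- njTree(plastomeDistances(msa))

  colMin <- apply(E, 2L, min)
  colMax <- apply(E, 2L, max)
  boring <- colMin > 0L & colMin == colMax      # invariant, no missing
  interesting <- which(!boring)
  EI <- E[, interesting, drop = FALSE]
  pairs <- utils::combn(k, 2L)
  nP <- ncol(pairs)
  diffI <- matrix(FALSE, nP, length(interesting))
  validI <- matrix(FALSE, nP, length(interesting))
  for (p in seq_len(nP)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    v <- EI[i, ] > 0L & EI[j, ] > 0L
    validI[p, ] <- v
    diffI[p, ] <- v & EI[i, ] != EI[j, ]
  }

  reps <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    set.seed(seed + r)
    w <- stats::rmultinom(1L, nCol, rep.int(1, nCol))[, 1L]
    wBoring <- sum(w[boring])
    wI <- w[interesting]
    dm <- matrix(0, k, k, dimnames = list(ids, ids))
    for (p in seq_len(nP)) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      denom <- wBoring + sum(wI[validI[p, ]])
      num <- sum(wI[diffI[p, ]])
      dm[i, j] <- dm[j, i] <- if (denom > 0) num / denom else 0
    }
    reps[[r]] <- njTree(dm)
  }
  cl <- ape::prop.clades(tree, reps, rooted = FALSE)
  cl[is.na(cl)] <- 0L
  tree$node.label <- round(100 * cl / nReps)
  tree
}

#' Is a taxon set monophyletic after rooting on an outgroup?
#'
#' @param tree a `phylo` tree containing the outgroup.
#' @param taxa taxon labels to test.
#' @param outgroupId taxon used to root the tree.
#' @return logical.
#' @export
isMonophyletic <- function(tree, taxa, outgroupId) {
  .check(all(c(taxa, outgroupId) %in% tree$tip.label),
         "taxa not in tree: %s",
         paste(setdiff(c(taxa, outgroupId), tree$tip.label), collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroupId, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Bootstrap support of the branch defining a taxon bipartition
#'
#' Looks up the internal-node support value (set by [bootstrapSupport()]) of
#' the branch splitting `taxa` from the remaining leaves; `NA` when the
#' bipartition is absent from the tree.
#'
#' @param tree a `phylo` with `node.label` support values.
#' @param taxa taxon labels on one side of the bipartition.
#' @return numeric support (percent), or `NA`.
#' @export
cladeSupport <- function(tree, taxa) {
  .check(!is.null(tree$node.label), "tree carries no support values")
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  comp <- setdiff(labels, taxa)
  for (i in seq_along(pp)) {
    tips <- labels[pp[[i]]]
    if (setequal(tips, taxa) || setequal(tips, comp))
      return(as.numeric(tree$node.label[i]))
  }
  NA_real_
}
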