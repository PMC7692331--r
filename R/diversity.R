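#' Polymorphic loci within a genotype subset
#'
#' A SNP site (or SSR locus) is polymorphic within the subset iff at least
#' two distinct non-missing alleles (repeat counts) occur among subset
#' members. The fraction is taken over the full panel's locus total and
#' reported as a percentage with one decimal.
#'
#' @param x a [VariantPanel-class] or [SsrTable-class].
#' @param subset genotype ids (at least two).
#' @return named numeric vector `c(count, fraction, total)`.
#' @export
setGeneric("polymorphicInSubset", function(x, subset) standardGeneric("polymorphicInSubset"))

.polyFromMatrix <- function(mat, subset) {
  .check(length(subset) >= 2L, "subset must contain at least two genotypes")
  .check(all(subset %in% rownames(mat)),
         "unknown genotypes: %s", paste(setdiff(subset, rownames(mat)), collapse = ", "))
  sub <- mat[subset, , drop = FALSE]
  nd <- apply(sub, 2L, function(v) length(unique(v[!is.na(v)])))
  count <- sum(nd >= 2L)
  total <- ncol(mat)
  c(count = count, fraction = round(100 * count / total, 1L), total = total)
}

#' @rdname polymorphicInSubset
#' @export
setMethod("polymorphicInSubset", "VariantPanel", function(x, subset) {
  .polyFromMatrix(x@alleles, subset)
})

#' @rdname polymorphicInSubset
#' @export
setMethod("polymorphicInSubset", "SsrTable", function(x, subset) {
  .polyFromMatrix(x@counts, subset)
})

#' Fold ratio of two polymorphism counts
#'
#' @param countA,countB non-negative counts; `countB` must be positive.
#' @return the ratio rounded to the nearest integer.
#' @examples
#' foldRatio(389, 16)  # 24
#' foldRatio(49, 12)   # 4
#' @export
foldRatio <- function(countA, countB) {
  .check(countB > 0, "zero denominator in fold ratio")
  round(countA / countB)
}

#' Loci with one shared uniform allele across two genotype subsets
#'
#' Counts loci where the (non-missing) alleles or repeat counts are uniform
#' and identical across the union of two disjoint subsets, each contributing
#' at least one non-missing value. Fraction over the full panel locus total.
#'
#' @param x a [VariantPanel-class] or [SsrTable-class].
#' @param subsetA,subsetB disjoint, non-empty genotype id vectors.
#' @return named numeric vector `c(count, fraction, total)`.
#' @export
setGeneric("sharedWithGroup", function(x, subsetA, subsetB) standardGeneric("sharedWithGroup"))

.sharedFromMatrix <- function(mat, subsetA, subsetB) {
  .check(length(subsetA) > 0L && length(subsetB) > 0L, "subsets must be non-empty")
  .check(length(intersect(subsetA, subsetB)) == 0L, "subsets must be disjoint")
  ok <- apply(mat[c(subsetA, subsetB), , drop = FALSE], 2L, function(v) {
    a <- v[seq_along(subsetA)]; b <- v[-seq_along(subsetA)]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    length(a) > 0L && length(b) > 0L && length(unique(c(a, b))) == 1L
  })
  count <- sum(ok)
  total <- ncol(mat)
  c(count = count, fraction = round(100 * count / total, 1L), total = total)
}

#' @rdname sharedWithGroup
#' @export
setMethod("sharedWithGroup", "VariantPanel", function(x, subsetA, subsetB) {
  .sharedFromMatrix(x@alleles, subsetA, subsetB)
})

#' @rdname sharedWithGroup
#' @export
setMethod("sharedWithGroup", "SsrTable", function(x, subsetA, subsetB) {
  .sharedFromMatrix(x@counts, subsetA, subsetB)
})

#' SNP counts per coding gene
#'
#' Counts variant sites whose context is `CDS:<gene>` over the full panel
#' site list (each site counted once, under its full gene label).
#'
#' @param vp a [VariantPanel-class] with `context` annotated.
#' @return named integer vector, gene -> SNP count.
#' @export
perGeneCounts <- function(vp) {
  stopifnot(is(vp, "VariantPanel"))
  .check("context" %in% names(vp@sites), "annotate context first")
  cds <- vp@sites$context[.contextClass(vp@sites$context) == "CDS"]
  if (length(cds) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(sub("^CDS:", "", cds))
  setNames(as.integer(tab), names(tab))
}

#' Pairwise SNP counts of every genotype against the reference
#'
#' Counts sites where the genotype carries a non-missing allele different
#' from the reference allele.
#'
#' @param vp a [VariantPanel-class].
#' @return named integer vector, genotype -> count.
#' @export
pairwiseCountsVsReference <- function(vp) {
  stopifnot(is(vp, "VariantPanel"))
  d <- .diffsVsReference(vp)
  setNames(as.integer(rowSums(d)), rownames(d))
}

#' Bottleneck diversity summary for a genotype subset
#'
#' @param vp a [VariantPanel-class] (context/region annotated for the
#'   per-context and per-region breakdowns).
#' @param subset genotype ids (>= 2).
#' @param label subset label for the output.
#' @return one-row data.frame: `subset`, `n_total`, `n_polymorphic`,
#'   `fraction`.
#' @export
diversitySummary <- function(vp, subset, label = "subset") {
  p <- polymorphicInSubset(vp, subset)
  data.frame(subset = label, n_total = p[["total"]],
             n_polymorphic = p[["count"]], fraction = p[["fraction"]],
             stringsAsFactors = FALSE)
}
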