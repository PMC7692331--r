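#' Construct a GroupScheme
#'
#' @param groups named character vector mapping genotype id to group label.
#' @param distantPanel genotype ids of the distant-wild outgroup panel (not
#'   members of any group).
#' @param referenceId genotype carrying the reference allele; must belong to a
#'   group.
#' @param groupLevels ordered group labels; defaults to the five-group layout
#'   used throughout the package.
#' @return a [GroupScheme-class] object.
#' @examples
#' groupScheme(
#'   groups = c(ref = "var_lycopersicum", loc1 = "local_accessions",
#'              cer = "var_cerasiforme", pim = "pimpinellifolium",
#'              hab = "wild_close"),
#'   distantPanel = c("out1", "out2"),
#'   referenceId = "ref"
#' )
#' @export
groupScheme <- function(groups, distantPanel, referenceId,
                        groupLevels = c("var_lycopersicum", "local_accessions",
                                        "var_cerasiforme", "pimpinellifolium",
                                        "wild_close")) {
  new("GroupScheme",
    groups = groups, groupLevels = groupLevels,
    distantPanel = as.character(distantPanel), referenceId = referenceId
  )
}

#' Construct a PlastomeAlignment
#'
#' @param rows named character vector or [Biostrings::DNAStringSet] of gapped
#'   rows (equal width, alphabet `{A,C,G,T,N,-}`).
#' @param referenceId name of the reference row.
#' @return a [PlastomeAlignment-class].
#' @export
plastomeAlignment <- function(rows, referenceId) {
  if (is.character(rows)) rows <- DNAStringSet(toupper(rows))
  new("PlastomeAlignment", aln = rows, referenceId = referenceId)
}

#' Genotype ids of a panel object
#' @param x a PlastomeAlignment, GroupScheme or SimulatedPanel.
#' @return character vector of genotype ids.
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))

#' @rdname genotypeIds
#' @export
setMethod("genotypeIds", "PlastomeAlignment", function(x) names(x@aln))

#' @rdname genotypeIds
#' @export
setMethod("genotypeIds", "GroupScheme", function(x) {
  c(names(x@groups), x@distantPanel)
})

#' @rdname genotypeIds
#' @export
setMethod("genotypeIds", "SimulatedPanel", function(x) names(x@sequences))

#' Reference genotype id
#' @param x a PlastomeAlignment, GroupScheme or SimulatedPanel.
#' @return a single genotype id.
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))

#' @rdname referenceId
#' @export
setMethod("referenceId", "PlastomeAlignment", function(x) x@referenceId)

#' @rdname referenceId
#' @export
setMethod("referenceId", "GroupScheme", function(x) x@referenceId)

#' @rdname referenceId
#' @export
setMethod("referenceId", "SimulatedPanel", function(x) x@scheme@referenceId)

#' Alignment as a character matrix
#'
#' @param x a PlastomeAlignment.
#' @return character matrix (genotypes x columns) of single characters.
#' @export
alignmentMatrix <- function(x) {
  stopifnot(is(x, "PlastomeAlignment"))
  m <- as.matrix(x@aln)
  rownames(m) <- names(x@aln)
  m
}

#' Region lengths of a quadripartite structure
#'
#' @param q a [QuadripartiteStructure-class].
#' @return named integer vector `c(total, lsc, ssc, ira, irb)`.
#' @export
regionLengths <- function(q) {
  stopifnot(is(q, "QuadripartiteStructure"))
  n <- q@genomeLength
  c(
    total = n,
    lsc = .circLen(q@lsc[1L], q@lsc[2L], n),
    ssc = .circLen(q@ssc[1L], q@ssc[2L], n),
    ira = .circLen(q@ira[1L], q@ira[2L], n),
    irb = .circLen(q@irb[1L], q@irb[2L], n)
  )
}

#' SNP site table of a VariantPanel
#' @param x a [VariantPanel-class].
#' @return data.frame of annotated SNP sites.
#' @export
variantSites <- function(x) {
  stopifnot(is(x, "VariantPanel"))
  x@sites
}

#' Per-genotype allele matrix of a VariantPanel
#' @param x a [VariantPanel-class].
#' @return character matrix (genotypes x sites); `NA` = missing.
#' @export
alleleMatrix <- function(x) {
  stopifnot(is(x, "VariantPanel"))
  x@alleles
}

#' Indel event table of a VariantPanel
#' @param x a [VariantPanel-class].
#' @return data.frame of indel events.
#' @export
indelEvents <- function(x) {
  stopifnot(is(x, "VariantPanel"))
  x@indels
}

#' Feature table of a PlastomeAnnotation
#' @param x a [PlastomeAnnotation-class].
#' @return the features GRanges.
#' @export
annotationFeatures <- function(x) {
  stopifnot(is(x, "PlastomeAnnotation"))
  x@features
}

setMethod("show", "GroupScheme", function(object) {
  cat("GroupScheme:", length(object@groups), "genotypes in",
      length(object@groupLevels), "groups +", length(object@distantPanel),
      "distant-panel genotypes\n")
  for (g in object@groupLevels) {
    ids <- names(object@groups)[object@groups == g]
    cat(sprintf("  %-20s %s\n", g, paste(ids, collapse = ", ")))
  }
  cat(sprintf("  %-20s %s\n", "distant_panel", paste(object@distantPanel, collapse = ", ")))
  cat("  reference:", object@referenceId, "\n")
})

setMethod("show", "PlastomeAlignment", function(object) {
  cat("PlastomeAlignment:", length(object@aln), "genotypes x",
      Biostrings::width(object@aln)[1L], "columns; reference:",
      object@referenceId, "\n")
})

setMethod("show", "QuadripartiteStructure", function(object) {
  l <- regionLengths(object)
  cat("QuadripartiteStructure (", l[["total"]], " bp):\n", sep = "")
  cat(sprintf("  LSC %6d..%-6d (%d bp)\n", object@lsc[1L], object@lsc[2L], l[["lsc"]]))
  cat(sprintf("  IRa %6d..%-6d (%d bp)\n", object@ira[1L], object@ira[2L], l[["ira"]]))
  cat(sprintf("  SSC %6d..%-6d (%d bp)\n", object@ssc[1L], object@ssc[2L], l[["ssc"]]))
  cat(sprintf("  IRb %6d..%-6d (%d bp)\n", object@irb[1L], object@irb[2L], l[["irb"]]))
})

setMethod("show", "VariantPanel", function(object) {
  cat("VariantPanel:", nrow(object@sites), "SNP sites,",
      nrow(object@indels), "indel events across",
      nrow(object@alleles), "genotypes; reference:", object@referenceId, "\n")
})

setMethod("show", "SimulatedPanel", function(object) {
  cat("SimulatedPanel:", length(object@sequences), "genotypes,",
      object@annotation@genomeLength, "bp reference\n")
  cat("  planted SNP sites:", nrow(object@truth$variant_truth), "\n")
  cat("  planted SSR loci: ", nrow(object@truth$ssr_truth), "\n")
  cat("  planted TR loci:  ", nrow(object@truth$tr_truth), "\n")
})
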