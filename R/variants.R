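#' Map alignment columns to reference coordinates
#'
#' Columns where the reference row has a base map to the cumulative count of
#' reference bases up to and including that column; columns where the
#' reference row is gapped are insertion anchors "after position p" (p = 0
#' for leading gaps). The mapping is monotone non-decreasing and total.
#'
#' @param msa a [PlastomeAlignment-class].
#' @return data.frame with columns `column`, `ref_position`, `is_insertion`.
#' @export
mapColumns <- function(msa) {
  stopifnot(is(msa, "PlastomeAlignment"))
  ref <- .toVec(as.character(msa@aln[[msa@referenceId]]))
  nonGap <- ref != "-"
  data.frame(
    column = seq_along(ref),
    ref_position = cumsum(nonGap),
    is_insertion = !nonGap
  )
}

#' Extract SNP sites and indel events from a plastome alignment
#'
#' A column is a SNP site iff the reference base is in `{A,C,G,T}` and at
#' least two distinct `{A,C,G,T}` bases occur across rows there; `N` and `-`
#' are treated as missing and never create or suppress a SNP. Maximal runs of
#' columns sharing one gap pattern are merged into single indel events.
#'
#' @param msa a [PlastomeAlignment-class].
#' @param ann optional [PlastomeAnnotation-class]; adds `context` and coding
#'   `effect`/`aa_change` columns (the latter need `refGenome`).
#' @param structure optional [QuadripartiteStructure-class]; adds `region`.
#' @param refGenome optional ungapped reference sequence (defaults to the
#'   degapped reference row) used for coding-effect calls and duplication
#'   flags.
#' @return a [VariantPanel-class].
#' @export
extractVariants <- function(msa, ann = NULL, structure = NULL, refGenome = NULL) {
  stopifnot(is(msa, "PlastomeAlignment"))
  M <- alignmentMatrix(msa)
  ids <- rownames(M)
  nc <- ncol(M)
  ref <- M[msa@referenceId, ]

  refGapRuns <- rle(ref == "-")
  if (any(refGapRuns$values & refGapRuns$lengths > nc / 2))
    stop("misalignment guard: all-gap reference column run longer than half the alignment",
         call. = FALSE)

  refPos <- cumsum(ref != "-")
  if (is.null(refGenome)) refGenome <- .fromVec(ref[ref != "-"])
  refGenome <- .asSequenceString(refGenome)

  # SNP columns: >= 2 distinct ACGT bases present and reference base in ACGT
  bases <- c("A", "C", "G", "T")
  present <- vapply(bases, function(b) colSums(M == b) > 0L, logical(nc))
  nDistinct <- rowSums(present)
  isSnp <- nDistinct >= 2L & ref %in% bases
  snpCols <- which(isSnp)

  alleles <- t(M[, snpCols, drop = FALSE])
  alleles[!(alleles %in% bases)] <- NA_character_
  alleles <- t(alleles)
  nAll <- apply(alleles, 2L, function(x) length(unique(x[!is.na(x)])))

  sites <- data.frame(
    column = snpCols,
    position = refPos[snpCols],
    ref = ref[snpCols],
    n_alleles = as.integer(nAll),
    stringsAsFactors = FALSE
  )

  # indel events: maximal column runs with a constant non-empty gap pattern
  gapM <- M == "-"
  key <- as.vector(2^(seq_along(ids) - 1L) %*% gapM)  # exact for <= 52 rows
  r <- rle(key)
  colStart <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  indels <- list()
  for (i in which(r$values != 0)) {
    colsRun <- seq.int(colStart[i], length.out = r$lengths[i])
    gapped <- ids[gapM[, colsRun[1L]]]
    refGapped <- msa@referenceId %in% gapped
    if (refGapped) {
      carriers <- ids[!gapM[, colsRun[1L]]]
      basesRun <- .fromVec(M[carriers[1L], colsRun])
      kind <- "insertion"
      pos <- refPos[colsRun[1L]]          # anchor: after this reference base
    } else {
      carriers <- gapped
      basesRun <- .fromVec(ref[colsRun])
      kind <- "deletion"
      pos <- refPos[colsRun[1L]] - 1L     # reference base before the event
    }
    indels[[length(indels) + 1L]] <- data.frame(
      position = pos, kind = kind, length = length(colsRun),
      bases = basesRun, genotypes = paste(sort(carriers), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(position = integer(), kind = character(), length = integer(),
               bases = character(), genotypes = character(),
               stringsAsFactors = FALSE)
  if (nrow(indels)) {
    indels <- indels[order(indels$position), , drop = FALSE]
    rownames(indels) <- NULL
    indels$is_tandem_duplication <- vapply(seq_len(nrow(indels)), function(i) {
      classifyIndelDuplication(indels[i, ], refGenome)
    }, logical(1))
  } else {
    indels$is_tandem_duplication <- logical(0)
  }

  vp <- new("VariantPanel", sites = sites, alleles = alleles,
            indels = indels, referenceId = msa@referenceId)
  if (!is.null(ann)) {
    vp@sites$context <- contextOf(vp@sites$position, ann)
    vp <- annotateEffects(vp, ann, refGenome)
  }
  if (!is.null(structure)) vp@sites$region <- regionOf(vp@sites$position, structure)
  vp
}

#' Is an insertion a tandem duplication of its flank?
#'
#' `TRUE` iff the inserted bases equal the reference bases immediately to the
#' left or to the right of the insertion anchor, over the same length.
#'
#' @param event one insertion row of [indelEvents()] (or a list with elements
#'   `position`, `kind`, `length`, `bases`).
#' @param refGenome the ungapped reference sequence.
#' @return logical.
#' @examples
#' ev <- list(position = 8, kind = "insertion", length = 4, bases = "ATAA")
#' classifyIndelDuplication(ev, "GGGGATAACCCC")  # TRUE: left flank is ATAA
#' @export
classifyIndelDuplication <- function(event, refGenome) {
  if (event$kind != "insertion") return(FALSE)
  s <- .asSequenceString(refGenome)
  n <- nchar(s)
  len <- event$length
  p <- event$position
  left <- if (p - len + 1L >= 1L) substr(s, p - len + 1L, p) else ""
  right <- if (p + len <= n) substr(s, p + 1L, p + len) else ""
  identical(event$bases, left) || identical(event$bases, right)
}

#' Annotate coding effects of SNP sites
#'
#' For sites whose context is the CDS of a translatable protein gene, the
#' affected codon is reconstructed strand-aware from the spliced CDS intervals
#' of the reference sequence with only this site's allele substituted, and
#' translated with the bacterial/plastid genetic code (translation table 11).
#' A site is synonymous iff the amino acid is unchanged for every alternative
#' allele; `aa_change` reports the first nonsynonymous alternative as
#' `X123Y`. Sites outside protein CDS get `not_applicable`; codons running
#' past the CDS end get `invalid_annotation`.
#'
#' @param vp a [VariantPanel-class] with `context` annotated.
#' @param ann a [PlastomeAnnotation-class].
#' @param refGenome the ungapped reference sequence.
#' @return the VariantPanel with `effect` and `aa_change` columns filled.
#' @export
annotateEffects <- function(vp, ann, refGenome) {
  stopifnot(is(vp, "VariantPanel"), is(ann, "PlastomeAnnotation"))
  .check("context" %in% names(vp@sites), "annotate context before effects")
  s <- .asSequenceString(refGenome)
  gr <- ann@features
  m <- mcols(gr)
  code <- Biostrings::getGeneticCode("11")

  effects <- rep("not_applicable", nrow(vp@sites))
  aaChange <- rep(NA_character_, nrow(vp@sites))

  cdsGenes <- unique(m$gene[m$kind == "CDS" & m$translatable %in% TRUE])
  cdsIdx <- which(.contextClass(vp@sites$context) == "CDS")
  for (i in cdsIdx) {
    genes <- strsplit(.contextGene(vp@sites$context[i]), "|", fixed = TRUE)[[1L]]
    genes <- genes[genes %in% cdsGenes]
    if (length(genes) == 0L) next     # tRNA/rRNA or non-translatable CDS
    g <- genes[1L]
    sel <- which(m$kind == "CDS" & m$gene == g)
    sel <- sel[order(m$exon_rank[sel])]
    strandG <- as.character(strand(gr))[sel[1L]]
    phase <- m$phase[sel[1L]]
    pos <- vp@sites$position[i]

    # CDS-relative index of the genomic position, in translation order
    cdsIndex <- NA_integer_
    offset <- 0L
    cdsLen <- 0L
    segs <- lapply(sel, function(j) c(start(gr)[j], end(gr)[j]))
    for (seg in segs) cdsLen <- cdsLen + (seg[2L] - seg[1L] + 1L)
    for (seg in segs) {
      w <- seg[2L] - seg[1L] + 1L
      if (pos >= seg[1L] && pos <= seg[2L]) {
        cdsIndex <- offset + if (strandG == "+") pos - seg[1L] + 1L else seg[2L] - pos + 1L
        break
      }
      offset <- offset + w
    }
    if (is.na(cdsIndex)) next
    cdsIndex <- cdsIndex - phase
    if (cdsIndex < 1L) { effects[i] <- "invalid_annotation"; next }
    codonIdx <- (cdsIndex - 1L) %/% 3L + 1L
    inCodon <- (cdsIndex - 1L) %% 3L + 1L
    if (codonIdx * 3L + phase > cdsLen) { effects[i] <- "invalid_annotation"; next }

    # genomic positions (translation order) of the codon
    cdsPositions <- unlist(lapply(segs, function(seg) {
      if (strandG == "+") seq.int(seg[1L], seg[2L]) else seq.int(seg[2L], seg[1L])
    }))
    codonGenomic <- cdsPositions[phase + (codonIdx - 1L) * 3L + 1:3]
    codonRef <- vapply(codonGenomic, function(p) substr(s, p, p), character(1))
    if (strandG == "-") codonRef <- .compVec(codonRef)

    refAllele <- vp@sites$ref[i]
    alts <- setdiff(unique(vp@alleles[, i]), c(refAllele, NA))
    if (length(alts) == 0L) next
    aaRef <- code[[.fromVec(codonRef)]]
    syn <- TRUE
    for (alt in alts) {
      codonAlt <- codonRef
      codonAlt[inCodon] <- if (strandG == "+") alt else .COMPLEMENT[[alt]]
      aaAlt <- code[[.fromVec(codonAlt)]]
      if (aaAlt != aaRef) {
        syn <- FALSE
        if (is.na(aaChange[i]))
          aaChange[i] <- paste0(aaRef, codonIdx, aaAlt)
      }
    }
    effects[i] <- if (syn) "synonymous" else "nonsynonymous"
  }
  vp@sites$effect <- effects
  vp@sites$aa_change <- aaChange
  vp
}

#' Per-genotype SNP counts split by genomic context
#'
#' Counts, for every genotype, the sites where its (non-missing) allele
#' differs from the reference allele, split by context class. Row totals
#' equal the genotype's pairwise SNP count against the reference.
#'
#' @param vp a [VariantPanel-class] with `context` annotated.
#' @return data.frame with columns `genotype`, `CDS`, `intron`, `intergenic`,
#'   `total`.
#' @export
countByContext <- function(vp) {
  stopifnot(is(vp, "VariantPanel"))
  .check("context" %in% names(vp@sites), "annotate context first")
  cls <- .contextClass(vp@sites$context)
  diff <- .diffsVsReference(vp)
  out <- data.frame(
    genotype = rownames(diff),
    CDS = as.integer(diff %*% (cls == "CDS")),
    intron = as.integer(diff %*% (cls == "intron")),
    intergenic = as.integer(diff %*% (cls == "intergenic")),
    stringsAsFactors = FALSE
  )
  out$total <- out$CDS + out$intron + out$intergenic
  out
}

# logical matrix genotypes x sites: allele present and different from ref
.diffsVsReference <- function(vp) {
  refs <- matrix(vp@sites$ref, nrow = nrow(vp@alleles), ncol = nrow(vp@sites),
                 byrow = TRUE)
  d <- vp@alleles != refs
  d[is.na(d)] <- FALSE
  rownames(d) <- rownames(vp@alleles)
  d
}

#' Write a VariantPanel as a site-level VCF 4.2
#'
#' Haploid site-level records with one `GT` column per genotype; missing
#' alleles are `.`.
#'
#' @param vp a [VariantPanel-class].
#' @param path output file.
#' @param seqid contig name.
#' @param contigLength contig length for the header.
#' @return `path`, invisibly.
#' @export
writeVariantsVcf <- function(vp, path, seqid = "plastome", contigLength = NULL) {
  sites <- vp@sites
  ids <- rownames(vp@alleles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=plastomeVar_%s", as.character(utils::packageVersion("plastomeVar"))),
    if (!is.null(contigLength)) sprintf("##contig=<ID=%s,length=%d>", seqid, contigLength)
      else sprintf("##contig=<ID=%s>", seqid),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(sites))) {
    al <- vp@alleles[, i]
    alts <- setdiff(unique(al[!is.na(al)]), sites$ref[i])
    gt <- ifelse(is.na(al), ".",
                 ifelse(al == sites$ref[i], "0", match(al, alts)))
    writeLines(paste(c(seqid, sites$position[i], ".", sites$ref[i],
                       paste(alts, collapse = ","), ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
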