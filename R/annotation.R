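#' Genomic context of reference positions
#'
#' Labels every queried position with exactly one context: `CDS:<gene>` when
#' the position lies in an exon interval of a gene (tRNA/rRNA exons count as
#' coding sequence for tally purposes), `intron:<gene>` when it lies inside a
#' gene's span but in none of that gene's exon intervals, and
#' `intergenic:<left>-<right>` otherwise, with flanking gene names wrapping
#' circularly at the genome ends. Context priority is CDS > intron >
#' intergenic; overlapping coding genes are reported joined by `|`.
#'
#' @param positions integer vector of 1-based reference coordinates.
#' @param ann a [PlastomeAnnotation-class].
#' @return character vector of context labels, one per position.
#' @export
contextOf <- function(positions, ann) {
  stopifnot(is(ann, "PlastomeAnnotation"))
  if (length(positions) == 0L) return(character(0))
  n <- ann@genomeLength
  .check(all(positions >= 1L & positions <= n),
         "position out of range [1, %d]", n)
  gr <- ann@features
  m <- mcols(gr)
  exons <- gr[m$kind %in% c("CDS", "tRNA", "rRNA")]
  spans <- gr[m$kind == "gene"]
  q <- GRanges("plastome", IRanges(positions, width = 1L))
  out <- character(length(positions))

  ovE <- GenomicRanges::findOverlaps(q, exons, ignore.strand = TRUE)
  if (length(ovE)) {
    hitGenes <- split(mcols(exons)$gene[S4Vectors::subjectHits(ovE)],
                      S4Vectors::queryHits(ovE))
    idx <- as.integer(names(hitGenes))
    out[idx] <- vapply(hitGenes, function(g) {
      paste0("CDS:", paste(sort(unique(g)), collapse = "|"))
    }, character(1))
  }

  todo <- which(out == "")
  if (length(todo)) {
    ovS <- GenomicRanges::findOverlaps(q[todo], spans, ignore.strand = TRUE)
    if (length(ovS)) {
      hitGenes <- split(mcols(spans)$gene[S4Vectors::subjectHits(ovS)],
                        S4Vectors::queryHits(ovS))
      idx <- todo[as.integer(names(hitGenes))]
      out[idx] <- vapply(hitGenes, function(g) {
        paste0("intron:", paste(sort(unique(g)), collapse = "|"))
      }, character(1))
    }
  }

  todo <- which(out == "")
  if (length(todo)) {
    .check(length(spans) > 0L, "annotation has no gene spans; cannot name intergenic flanks")
    ends <- sort(setNames(end(spans), mcols(spans)$gene)[order(end(spans))])
    starts <- setNames(start(spans), mcols(spans)$gene)
    starts <- starts[order(unname(starts))]
    endVals <- unname(ends); startVals <- unname(starts)
    for (i in todo) {
      p <- positions[i]
      li <- findInterval(p - 1L, endVals)            # last gene ending before p
      left <- if (li >= 1L) names(ends)[li] else names(ends)[length(ends)]
      ri <- findInterval(p, startVals) + 1L          # first gene starting after p
      right <- if (ri <= length(starts)) names(starts)[ri] else names(starts)[1L]
      out[i] <- paste0("intergenic:", left, "-", right)
    }
  }
  out
}

# Collapse a full context label to its class (CDS / intron / intergenic).
.contextClass <- function(context) {
  sub(":.*$", "", context)
}

#' Gene name carried by a CDS/intron context label, NA for intergenic
#' @keywords internal
.contextGene <- function(context) {
  ifelse(.contextClass(context) %in% c("CDS", "intron"),
         sub("^[^:]+:", "", context), NA_character_)
}
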