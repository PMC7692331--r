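#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
NULL

#' GroupScheme: genotype-to-group assignment with a distant outgroup panel
#'
#' Assigns every genotype of a plastome panel to one of five ordered in-groups
#' (by default `var_lycopersicum`, `local_accessions`, `var_cerasiforme`,
#' `pimpinellifolium`, `wild_close`) or to the distant-wild outgroup panel used
#' for allele polarization. One in-group member is the reference genotype.
#'
#' @slot groups named character vector, genotype id -> group label.
#' @slot groupLevels ordered character vector of group labels.
#' @slot distantPanel character vector of genotype ids forming the outgroup
#'   panel (disjoint from the groups).
#' @slot referenceId id of the genotype carrying the reference allele.
#' @exportClass GroupScheme
setClass("GroupScheme",
  representation(
    groups = "character",
    groupLevels = "character",
    distantPanel = "character",
    referenceId = "character"
  )
)

setValidity("GroupScheme", function(object) {
  g <- object@groups
  if (is.null(names(g)) || anyDuplicated(names(g)))
    return("groups must be a named vector with unique genotype ids")
  if (!all(g %in% object@groupLevels))
    return("every group label must be one of groupLevels")
  if (!all(object@groupLevels %in% g))
    return("every group must be non-empty")
  if (any(object@distantPanel %in% names(g)))
    return("distant panel and groups must be disjoint")
  if (length(object@referenceId) != 1L || !(object@referenceId %in% names(g)))
    return("referenceId must be a member of exactly one group")
  TRUE
})

#' PlastomeAlignment: a multiple sequence alignment of complete plastomes
#'
#' Equal-width rows over `{A,C,G,T,N,-}` with a designated reference genotype.
#'
#' @slot aln [Biostrings::DNAStringSet] of equal-width gapped sequences, one
#'   per genotype, named by genotype id.
#' @slot referenceId the reference genotype id (must be a row name).
#' @exportClass PlastomeAlignment
setClass("PlastomeAlignment",
  representation(aln = "DNAStringSet", referenceId = "character")
)

setValidity("PlastomeAlignment", function(object) {
  w <- Biostrings::width(object@aln)
  if (length(w) < 1L) return("alignment must contain at least one row")
  if (length(unique(w)) != 1L) return("all alignment rows must have equal length")
  nm <- names(object@aln)
  if (is.null(nm) || anyDuplicated(nm)) return("genotype ids must be unique row names")
  if (!(object@referenceId %in% nm)) return("referenceId must name an alignment row")
  ref <- as.character(object@aln[[object@referenceId]])
  if (!grepl("[ACGT]", ref)) return("reference row must contain at least one non-gap base")
  TRUE
})

#' PlastomeAnnotation: gene/CDS features of a reference plastome
#'
#' Features are held as a [GenomicRanges::GRanges] with metadata columns
#' `feature_id`, `gene`, `kind` (one of `gene`, `CDS`, `tRNA`, `rRNA`,
#' `intron`), `phase` (codon start phase, 0/1/2) and `translatable` (logical,
#' protein CDS whose summed length is divisible by 3 after phase adjustment).
#' Multi-interval (spliced) CDS share one `feature_id`; interval rank in
#' translation order is in column `exon_rank`. Coordinates are 1-based
#' inclusive.
#'
#' @slot features GRanges of feature intervals.
#' @slot genomeLength integer length of the circular genome.
#' @exportClass PlastomeAnnotation
setClass("PlastomeAnnotation",
  representation(features = "GRanges", genomeLength = "integer")
)

setValidity("PlastomeAnnotation", function(object) {
  gr <- object@features
  need <- c("feature_id", "gene", "kind", "phase", "exon_rank", "translatable")
  if (!all(need %in% colnames(mcols(gr))))
    return(paste("features must carry metadata columns:", paste(need, collapse = ", ")))
  if (length(gr) && (min(start(gr)) < 1L || max(end(gr)) > object@genomeLength))
    return("every feature interval must lie within [1, genomeLength]")
  if (!all(mcols(gr)$kind %in% c("gene", "CDS", "tRNA", "rRNA", "intron")))
    return("kind must be one of gene, CDS, tRNA, rRNA, intron")
  TRUE
})

#' QuadripartiteStructure: LSC/SSC/IRa/IRb partition of a circular plastome
#'
#' Each region is a 1-based inclusive interval on the circular genome; an
#' interval whose end is smaller than its start wraps through the origin.
#'
#' @slot lsc,ssc,ira,irb integer vectors `c(start, end)`.
#' @slot genomeLength total genome length in bp.
#' @slot canonicalOrder `TRUE` when regions appear as LSC, IRa, SSC, IRb along
#'   the input linearization.
#' @exportClass QuadripartiteStructure
setClass("QuadripartiteStructure",
  representation(
    lsc = "integer", ssc = "integer", ira = "integer", irb = "integer",
    genomeLength = "integer", canonicalOrder = "logical"
  )
)

setValidity("QuadripartiteStructure", function(object) {
  n <- object@genomeLength
  lens <- vapply(
    list(object@lsc, object@ssc, object@ira, object@irb),
    function(iv) .circLen(iv[1L], iv[2L], n), integer(1)
  )
  if (sum(lens) != n)
    return("region lengths must sum to the genome length")
  if (lens[3L] != lens[4L]) return("the two inverted repeats must have equal length")
  if (lens[1L] <= lens[2L]) return("LSC must be longer than SSC")
  TRUE
})

#' VariantPanel: SNP sites and indel events extracted from an alignment
#'
#' @slot sites data.frame with one row per SNP site: `column` (alignment
#'   column), `position` (1-based reference coordinate), `ref` (reference
#'   allele), `n_alleles`, and once annotated `context`, `region`, `effect`,
#'   `aa_change`.
#' @slot alleles character matrix, genotypes x sites; `NA` marks a missing
#'   allele (gap or N).
#' @slot indels data.frame with one row per indel event: `position` (reference
#'   base before the event), `kind` (`insertion`/`deletion`), `length`,
#'   `bases`, `genotypes` (comma-joined carrier ids), `is_tandem_duplication`.
#' @slot referenceId reference genotype id.
#' @exportClass VariantPanel
setClass("VariantPanel",
  representation(
    sites = "data.frame", alleles = "matrix",
    indels = "data.frame", referenceId = "character"
  )
)

setValidity("VariantPanel", function(object) {
  if (nrow(object@sites) != ncol(object@alleles))
    return("alleles must have one column per variant site")
  TRUE
})

#' SsrTable: cross-genotype SSR locus table
#'
#' One row per merged SSR locus on reference coordinates, with per-genotype
#' repeat-unit counts recounted from each genotype's own (ungapped) sequence.
#'
#' @slot loci data.frame: `ref_start`, `ref_end`, `motif` (canonical), `unit`,
#'   `polymorphic`, plus `context`/`region` when annotated.
#' @slot counts integer matrix genotypes x loci of repeat-unit counts (`NA`
#'   where the genotype has no sequence at the locus).
#' @slot meets logical matrix genotypes x loci: count meets the detection
#'   threshold for the locus' unit size.
#' @exportClass SsrTable
setClass("SsrTable",
  representation(loci = "data.frame", counts = "matrix", meets = "matrix")
)

setValidity("SsrTable", function(object) {
  if (nrow(object@loci) != ncol(object@counts))
    return("counts must have one column per locus")
  TRUE
})

#' SimulatedPanel: a synthetic plastome panel with planted truth
#'
#' Bundle returned by [simulatePanel()]: the true gapped alignment, ungapped
#' per-genotype sequences, reference annotation, quadripartite structure,
#' group scheme, the species tree the mutations were placed on, and the truth
#' tables used to score recovery.
#'
#' @slot alignment PlastomeAlignment (the true MSA; gap columns known).
#' @slot sequences ungapped [Biostrings::DNAStringSet], one per genotype.
#' @slot annotation PlastomeAnnotation of the reference genotype.
#' @slot structure QuadripartiteStructure of the reference genotype.
#' @slot scheme GroupScheme for the panel.
#' @slot tree the species tree (class `phylo`) mutations were placed on.
#' @slot truth list of truth tables (see [simulatePanel()]).
#' @slot config the [simulationConfig()] used.
#' @exportClass SimulatedPanel
setClass("SimulatedPanel",
  representation(
    alignment = "PlastomeAlignment",
    sequences = "DNAStringSet",
    annotation = "PlastomeAnnotation",
    structure = "QuadripartiteStructure",
    scheme = "GroupScheme",
    tree = "ANY",
    truth = "list",
    config = "list"
  )
)
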