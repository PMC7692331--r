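#' Simulation configuration for a synthetic plastome panel
#'
#' The defaults are the study conditions emulated throughout the package: a
#' ~155 kb circular quadripartite genome, a 21-genotype panel in five groups
#' plus a five-genotype distant outgroup panel, 454 planted SNP sites whose
#' sharing-pattern categories count 271/90/38/5/2 (the remaining 48 sites are
#' private or lineage patterns outside the five categories), 114 SSR loci
#' (12 polymorphic among cultivated genotypes, 47 among wild, 74 shared
#' between cultivated and pimpinellifolium), 17 perfect tandem repeats with
#' periods 13-26 bp, one 1-bp deletion private to the third local accession
#' and one `(ATAA)2` tandem duplication private to the local accessions.
#'
#' @param seed integer seed; generation is a pure function of the config.
#' @param genome_length,ir_length,ssc_length region sizes in bp (LSC is the
#'   remainder).
#' @param gc GC content of the random background.
#' @param group_sizes named integer vector: sizes of the five groups and the
#'   distant panel.
#' @param category_counts planted counts for the five sharing categories.
#' @param other_counts planted counts for the non-category site patterns
#'   (private and lineage-internal mutations).
#' @param ssr_classes planted SSR locus counts per repeat-count pattern class.
#' @param n_tr number of planted perfect tandem repeats.
#' @param tr_periods period range for planted tandem repeats.
#' @param n_filler_genes unnamed 900-bp CDS genes added to the fixed gene
#'   roster.
#' @param ataa_duplication plant the local-private `(ATAA)2` duplication.
#' @param pgl_deletion plant the 1-bp deletion private to the third local
#'   accession.
#' @return a config list.
#' @export
simulationConfig <- function(seed = 1L,
                             genome_length = 155000L,
                             ir_length = 25600L,
                             ssc_length = 18400L,
                             gc = 0.38,
                             group_sizes = c(var_lycopersicum = 2L,
                                             local_accessions = 7L,
                                             var_cerasiforme = 2L,
                                             pimpinellifolium = 2L,
                                             wild_close = 3L,
                                             distant = 5L),
                             category_counts = c(lineage_ancestral = 271L,
                                                 pimpinellifolium_lineage = 90L,
                                                 de_novo_cultivated = 38L,
                                                 commercial_lineage_specific = 5L,
                                                 local_diagnostic = 2L),
                             other_counts = c(m82_private = 6L,
                                              cor_private = 1L,
                                              cer2_private = 2L,
                                              pim1_private = 5L,
                                              pim2_private = 5L,
                                              pim_pair = 0L,
                                              cer1_pim_clade = 18L,
                                              wild_shared = 11L),
                             ssr_classes = c(ancestral = 67L,
                                             lineage_shared = 7L,
                                             local_diagnostic = 1L,
                                             vlyc_diagnostic = 1L,
                                             cer2_mixed = 5L,
                                             m82_mixed = 5L,
                                             pim_shift = 28L),
                             n_tr = 17L,
                             tr_periods = c(13L, 26L),
                             n_filler_genes = 7L,
                             ataa_duplication = TRUE,
                             pgl_deletion = TRUE) {
  .check(ir_length >= 1000L, "ir_length below the minimum detectable IR (1000 bp)")
  .check(genome_length > 2L * ir_length + ssc_length,
         "region lengths inconsistent with genome_length")
  lsc <- genome_length - 2L * ir_length - ssc_length
  .check(lsc > ssc_length, "LSC must be longer than SSC")
  .check(all(category_counts >= 0L) && all(other_counts >= 0L) &&
           all(ssr_classes >= 0L), "planted counts must be non-negative")
  .check(all(group_sizes >= 1L), "group sizes must be at least 1")
  .check(group_sizes[["var_cerasiforme"]] >= 2L,
         "the cerasiforme group needs two genotypes (cer1/cer2 roles)")
  .check(group_sizes[["pimpinellifolium"]] >= 2L,
         "the pimpinellifolium group needs two genotypes")
  list(seed = as.integer(seed), genome_length = as.integer(genome_length),
       ir_length = as.integer(ir_length), ssc_length = as.integer(ssc_length),
       lsc_length = as.integer(lsc), gc = gc, group_sizes = group_sizes,
       category_counts = category_counts, other_counts = other_counts,
       ssr_classes = ssr_classes, n_tr = as.integer(n_tr),
       tr_periods = as.integer(tr_periods),
       n_filler_genes = as.integer(n_filler_genes),
       ataa_duplication = isTRUE(ataa_duplication),
       pgl_deletion = isTRUE(pgl_deletion))
}

# Genotype roster with the roles the planted patterns rely on.
.simRoster <- function(config) {
  gs <- config$group_sizes
  nm <- function(base, k, fixed) {
    if (k <= length(fixed)) fixed[seq_len(k)] else
      c(fixed, paste0(base, seq.int(length(fixed) + 1L, k)))
  }
  vlyc <- nm("vlyc", gs[["var_lycopersicum"]], c("IPA6", "M82"))
  loc <- nm("loc", gs[["local_accessions"]],
            c("cor", "pds", "pgl", "pol", "ves2001", "vfr", "vpz"))
  cer <- nm("cer", gs[["var_cerasiforme"]], c("cer1", "cer2"))
  pim <- nm("pim", gs[["pimpinellifolium"]], c("pim1", "pim2"))
  wild <- nm("wild", gs[["wild_close"]], c("habro", "chees", "galap"))
  dist <- nm("dist", gs[["distant"]], c("penn", "neor1", "neor2", "peru", "chil"))
  groups <- c(
    setNames(rep("var_lycopersicum", length(vlyc)), vlyc),
    setNames(rep("local_accessions", length(loc)), loc),
    setNames(rep("var_cerasiforme", length(cer)), cer),
    setNames(rep("pimpinellifolium", length(pim)), pim),
    setNames(rep("wild_close", length(wild)), wild)
  )
  list(vlyc = vlyc, loc = loc, cer = cer, pim = pim, wild = wild, dist = dist,
       ids = c(vlyc, loc, cer, pim, wild, dist),
       scheme = groupScheme(groups, dist, vlyc[1L]))
}

# Fixed gene roster plus filler CDS genes. Spans are genomic element widths
# (exons + intron for the two spliced genes).
.simGeneRoster <- function(config) {
  g <- function(gene, kind, region, strand, exons, intron = 0L) {
    data.frame(gene = gene, kind = kind, region = region, strand = strand,
               exon_lens = I(list(exons)), intron = intron,
               span = sum(exons) + intron, stringsAsFactors = FALSE)
  }
  # compact gene lengths for scaled-down genomes keep the same roster shape
  smallL <- config$lsc_length < 30000L
  smallS <- config$ssc_length < 12000L
  roster <- rbind(
    g("matK", "CDS", "LSC", "+", if (smallL) 600L else 1500L),
    g("rpoC1", "CDS", "LSC", "-", if (smallL) c(300L, 150L) else c(1638L, 432L),
      intron = if (smallL) 200L else 750L),
    g("rbcL", "CDS", "LSC", "+", if (smallL) 450L else 1428L),
    g("psbA", "CDS", "LSC", "-", if (smallL) 300L else 1062L),
    g("atpB", "CDS", "LSC", "-", if (smallL) 450L else 1497L),
    g("rps16", "CDS", "LSC", "-", if (smallL) c(120L, 42L) else c(225L, 42L),
      intron = if (smallL) 200L else 860L),
    g("rps4", "CDS", "LSC", "-", if (smallL) 300L else 606L),
    g("trnQ", "tRNA", "LSC", "-", 72L),
    g("trnV", "tRNA", "LSC", "+", 72L),
    g("trnE", "tRNA", "LSC", "+", 72L),
    g("trnH", "tRNA", "LSC", "+", 72L),
    g("ycf1", "CDS", "SSC", "+", if (smallS) 900L else 4500L),
    g("ndhH", "CDS", "SSC", "+", if (smallS) 480L else 1182L),
    g("ndhF", "CDS", "SSC", "-", if (smallS) 600L else 2220L),
    g("rrn16", "rRNA", "SSC", "+", if (smallS) 300L else 1491L)
  )
  if (config$n_filler_genes > 0L) {
    for (i in seq_len(config$n_filler_genes)) {
      roster <- rbind(roster, g(sprintf("orf%02d", i), "CDS", "LSC", "+", 900L))
    }
  }
  roster
}

# Random DNA vector at the configured GC content.
.simRandomBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# SSR locus plan: motif, unit, reference unit count, pattern class.
.simSsrPlan <- function(config) {
  cls <- config$ssr_classes
  polyN <- sum(cls) - cls[["ancestral"]]
  rows <- list()
  add <- function(class_, motif, unit, refUnits) {
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class_, motif = motif, unit = unit, ref_units = refUnits,
      stringsAsFactors = FALSE)
  }
  monoBases <- c("A", "T")
  # polymorphic classes: mono-nucleotide loci (unit deltas are 1-bp events)
  polyClasses <- setdiff(names(cls), "ancestral")
  ki <- 0L
  for (cl in polyClasses) {
    for (i in seq_len(cls[[cl]])) {
      ki <- ki + 1L
      # diagnostic loci sit at 9 units so the k-2 haplotype of the distant
      # panel drops below the 1/8 detection threshold (recount still sees it)
      add(cl, monoBases[1L + ki %% 2L], 1L,
          if (cl %in% c("local_diagnostic", "vlyc_diagnostic")) 9L else 9L + ki %% 4L)
    }
  }
  # ancestral loci: mono/di dominated, a few tri/tetra
  nAnc <- cls[["ancestral"]]
  nDi <- round(0.36 * nAnc); nTri <- round(0.09 * nAnc); nTet <- round(0.06 * nAnc)
  nMono <- nAnc - nDi - nTri - nTet
  for (i in seq_len(nMono)) add("ancestral", monoBases[1L + i %% 2L], 1L, 8L + i %% 5L)
  for (i in seq_len(nDi)) add("ancestral", "AT", 2L, 6L + i %% 3L)
  for (i in seq_len(nTri)) add("ancestral", "AAT", 3L, 5L)
  for (i in seq_len(nTet)) add("ancestral", "AAAT", 4L, 5L)
  plan <- do.call(rbind, rows)
  plan$locus_id <- sprintf("ssr%03d", seq_len(nrow(plan)))
  plan$array_len <- plan$unit * plan$ref_units
  attr(plan, "n_polymorphic") <- polyN
  plan
}

# Per-genotype SSR unit counts implied by each pattern class (all deltas are
# deletions relative to the reference count, so the true MSA needs insertion
# columns only for the ATAA duplication).
.simSsrCounts <- function(plan, roster) {
  ids <- roster$ids
  counts <- matrix(rep(plan$ref_units, each = length(ids)),
                   nrow = length(ids), ncol = nrow(plan),
                   dimnames = list(ids, plan$locus_id))
  for (li in seq_len(nrow(plan))) {
    k <- plan$ref_units[li]
    cl <- plan$class[li]
    if (cl == "ancestral") next
    if (cl == "lineage_shared") {
      counts[roster$dist, li] <- k - 1L
    } else if (cl == "local_diagnostic") {
      counts[roster$loc, li] <- k - 1L
      counts[roster$dist, li] <- k - 2L
    } else if (cl == "vlyc_diagnostic") {
      counts[setdiff(ids, roster$vlyc), li] <- k - 1L
      counts[roster$dist, li] <- k - 2L
    } else if (cl == "cer2_mixed") {
      counts[roster$cer[2L], li] <- k - 1L
      counts[roster$dist, li] <- k - 1L
    } else if (cl == "m82_mixed") {
      counts[roster$vlyc[2L], li] <- k - 1L
      counts[roster$pim[1L], li] <- k - 1L
    } else if (cl == "pim_shift") {
      counts[roster$pim, li] <- k - 1L
      if (li %% 2L == 0L) counts[roster$cer[1L], li] <- k - 1L
    } else {
      stop("unknown SSR class: ", cl)
    }
  }
  counts
}

# Tandem repeat plan: period and a unit free of SSR-like substructure.
.simTrPlan <- function(config) {
  periods <- rep(seq.int(config$tr_periods[1L], config$tr_periods[2L]),
                 length.out = config$n_tr)
  units <- character(config$n_tr)
  for (i in seq_len(config$n_tr)) {
    repeat {
      u <- .fromVec(.simRandomBases(periods[i], config$gc))
      if (.primitivePeriod(u) != periods[i]) next
      probe <- strrep(u, 3L)
      if (nrow(findSSRs(probe, circular = FALSE)) > 0L) next
      r <- rle(.toVec(probe))
      if (max(r$lengths) > 3L) next
      break
    }
    units[i] <- u
  }
  data.frame(tr_id = sprintf("tr%02d", seq_len(config$n_tr)),
             period = periods, unit = units, copies = 2L,
             array_len = 2L * periods, stringsAsFactors = FALSE)
}

# The site-pattern blueprint: carriers of the alternative allele per class.
.simCarrierSets <- function(roster) {
  list(
    lineage_ancestral = roster$dist,
    pimpinellifolium_lineage = c(roster$wild, roster$dist),
    de_novo_cultivated = c(roster$cer[1L], roster$pim, roster$wild, roster$dist),
    commercial_lineage_specific = c(roster$loc, roster$cer[1L], roster$pim,
                                    roster$wild, roster$dist),
    local_diagnostic = roster$loc,
    m82_private = roster$vlyc[2L],
    cor_private = roster$loc[1L],
    cer2_private = roster$cer[2L],
    pim1_private = roster$pim[1L],
    pim2_private = roster$pim[2L],
    pim_pair = roster$pim,
    cer1_pim_clade = c(roster$cer[1L], roster$pim),
    wild_shared = c(roster$pim, roster$wild, roster$dist)
  )
}

# Species tree the planted mutations are consistent with (category sites are
# single-origin on it; the wild_shared pattern is a documented reversion).
.simTrueTree <- function(roster, pimPairResolved = FALSE) {
  pimClade <- if (pimPairResolved) {
    sprintf("(%s,(%s))", roster$cer[1L], paste(roster$pim, collapse = ","))
  } else {
    sprintf("(%s,%s)", roster$cer[1L], paste(roster$pim, collapse = ","))
  }
  nwk <- sprintf("((%s),%s,(%s,((%s),(%s))));",
                 paste(roster$dist, collapse = ","),
                 paste(roster$wild, collapse = ","),
                 pimClade,
                 paste(roster$loc, collapse = ","),
                 paste(c(roster$vlyc, roster$cer[2L]), collapse = ","))
  ape::read.tree(text = nwk)
}
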