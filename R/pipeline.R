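# cheap stable hash of the effective configuration for output headers
.configHash <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  sprintf("%08x", sum(as.numeric(raw) * seq_along(raw)) %% 0xFFFFFFFF)
}

.stageStop <- function(stage, fmt, ...) {
  stop(sprintf("[stage %s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

# write a table with the package's commented header convention
.writeTsv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full comparative-plastome pipeline
#'
#' Executes structure detection, variant extraction, repeat haplotyping,
#' sharing-pattern classification, bottleneck statistics and the
#' neighbor-joining phylogeny, writing every stage's tables plus a summary
#' report under `outDir`.
#'
#' @param alignment a [PlastomeAlignment-class], or the path to an aligned
#'   FASTA (then `referenceId` must be given).
#' @param annotation a [PlastomeAnnotation-class] or GFF3 path.
#' @param scheme a [GroupScheme-class] or group-scheme file path
#'   (see [readGroupScheme()]).
#' @param outDir output directory (created if absent).
#' @param referenceId reference genotype id when `alignment` is a path.
#' @param cultivatedSubset genotype ids for the cultivated-bottleneck
#'   statistics; default: var_lycopersicum + local_accessions +
#'   var_cerasiforme without its first member (the wild-behaving accession).
#' @param minIrLen minimum inverted-repeat length for structure detection.
#' @param thresholds SSR thresholds ([ssrThresholds()]).
#' @param bootstrapReps,seed bootstrap replicates and RNG seed.
#' @return (invisibly) a list with every stage result and the report lines.
#' @export
runFullPipeline <- function(alignment, annotation, scheme, outDir,
                            referenceId = NULL,
                            cultivatedSubset = NULL,
                            minIrLen = 1000L,
                            thresholds = ssrThresholds(),
                            bootstrapReps = 100L, seed = 1L) {
  if (is.character(alignment)) {
    if (!file.exists(alignment)) .stageStop("input", "alignment file not found: %s", alignment)
    .check(!is.null(referenceId), "referenceId required when alignment is a path")
    alignment <- readAlignment(alignment, referenceId)
  }
  if (is.character(annotation)) {
    if (!file.exists(annotation)) .stageStop("input", "annotation file not found: %s", annotation)
    annotation <- readAnnotationGff(annotation)
  }
  if (is.character(scheme)) {
    if (!file.exists(scheme)) .stageStop("input", "group scheme file not found: %s", scheme)
    scheme <- readGroupScheme(scheme)
  }
  stopifnot(is(alignment, "PlastomeAlignment"), is(annotation, "PlastomeAnnotation"),
            is(scheme, "GroupScheme"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(minIrLen = minIrLen, thresholds = thresholds,
              bootstrapReps = bootstrapReps, seed = seed,
              reference = referenceId(alignment))
  meta <- sprintf("plastomeVar %s config=%s seed=%d",
                  as.character(utils::packageVersion("plastomeVar")),
                  .configHash(cfg), as.integer(seed))
  ids <- genotypeIds(alignment)
  M <- alignmentMatrix(alignment)
  seqs <- DNAStringSet(vapply(ids, function(g)
    paste(M[g, ][M[g, ] != "-"], collapse = ""), character(1)))
  names(seqs) <- ids

  # ---- structure -----------------------------------------------------------
  structures <- tryCatch(
    lapply(setNames(ids, ids), function(g)
      detectQuadripartite(as.character(seqs[[g]]), minIrLen = minIrLen)),
    error = function(e) .stageStop("structure", "%s", conditionMessage(e)))
  refStructure <- structures[[referenceId(alignment)]]
  st <- structureTable(structures)
  .writeTsv(st, file.path(outDir, "structure.tsv"), meta)
  .writeTsv(regionsToBed(refStructure), file.path(outDir, "regions.bed"), meta)

  # ---- variants ------------------------------------------------------------
  vp <- tryCatch(
    extractVariants(alignment, ann = annotation, structure = refStructure),
    error = function(e) .stageStop("variants", "%s", conditionMessage(e)))
  .writeTsv(variantSites(vp), file.path(outDir, "snp_sites.tsv"), meta)
  .writeTsv(indelEvents(vp), file.path(outDir, "indels.tsv"), meta)
  writeVariantsVcf(vp, file.path(outDir, "variants.vcf"),
                   contigLength = annotation@genomeLength)
  ctx <- countByContext(vp)
  .writeTsv(ctx, file.path(outDir, "context_counts.tsv"), meta)

  # ---- repeats -------------------------------------------------------------
  ssr <- tryCatch(
    buildSsrLocusTable(alignment, thresholds = thresholds,
                       ann = annotation, structure = refStructure),
    error = function(e) .stageStop("ssr", "%s", conditionMessage(e)))
  ssrOut <- cbind(ssr@loci, t(ssr@counts))
  .writeTsv(ssrOut, file.path(outDir, "ssr_loci.tsv"), meta)
  trTabs <- tryCatch(
    lapply(setNames(ids, ids), function(g)
      findTandemRepeats(as.character(seqs[[g]]))),
    error = function(e) .stageStop("tr", "%s", conditionMessage(e)))
  trAll <- do.call(rbind, lapply(ids, function(g) {
    t0 <- trTabs[[g]]
    if (nrow(t0) == 0L) return(NULL)
    cbind(genotype = g, t0)
  }))
  if (is.null(trAll)) trAll <- data.frame(genotype = character())
  .writeTsv(trAll, file.path(outDir, "tandem_repeats.tsv"), meta)

  # ---- classification ------------------------------------------------------
  cls <- tryCatch(classifyVariants(vp, scheme),
                  error = function(e) .stageStop("classify", "%s", conditionMessage(e)))
  .writeTsv(cls$classification, file.path(outDir, "snp_classification.tsv"), meta)
  .writeTsv(data.frame(category = names(cls$counts), n = as.integer(cls$counts)),
            file.path(outDir, "snp_category_counts.tsv"), meta)
  ssrCls <- classifySsrPatterns(ssr, scheme)
  .writeTsv(ssrCls, file.path(outDir, "ssr_classification.tsv"), meta)

  # ---- diversity statistics ------------------------------------------------
  grp <- scheme@groups
  cerIds <- names(grp)[grp == "var_cerasiforme"]
  if (is.null(cultivatedSubset)) {
    cultivatedSubset <- c(names(grp)[grp %in% c("var_lycopersicum", "local_accessions")],
                          cerIds[-1L])
  }
  wildSubset <- c(names(grp)[grp %in% c("pimpinellifolium", "wild_close")],
                  scheme@distantPanel)
  pimSubset <- names(grp)[grp == "pimpinellifolium"]
  stats <- tryCatch(list(
    snp_cultivated = polymorphicInSubset(vp, cultivatedSubset),
    snp_wild = polymorphicInSubset(vp, wildSubset),
    snp_shared = sharedWithGroup(vp, cultivatedSubset, pimSubset),
    ssr_cultivated = polymorphicInSubset(ssr, cultivatedSubset),
    ssr_wild = polymorphicInSubset(ssr, wildSubset),
    ssr_shared = sharedWithGroup(ssr, cultivatedSubset, pimSubset)
  ), error = function(e) .stageStop("stats", "%s", conditionMessage(e)))
  stats$snp_fold <- foldRatio(stats$snp_wild[["count"]], stats$snp_cultivated[["count"]])
  stats$ssr_fold <- foldRatio(stats$ssr_wild[["count"]], stats$ssr_cultivated[["count"]])
  perGene <- perGeneCounts(vp)
  .writeTsv(data.frame(gene = names(perGene), n_snps = as.integer(perGene)),
            file.path(outDir, "per_gene_counts.tsv"), meta)
  pw <- pairwiseCountsVsReference(vp)
  .writeTsv(data.frame(genotype = names(pw), snps_vs_reference = as.integer(pw)),
            file.path(outDir, "pairwise_counts.tsv"), meta)

  # ---- phylogeny -----------------------------------------------------------
  dm <- tryCatch(plastomeDistances(alignment),
                 error = function(e) .stageStop("tree", "%s", conditionMessage(e)))
  dOut <- data.frame(taxon = rownames(dm$d), dm$d, check.names = FALSE)
  .writeTsv(dOut, file.path(outDir, "distances.tsv"), meta)
  tree <- njTree(dm)
  tree <- bootstrapSupport(alignment, nReps = bootstrapReps, seed = seed, tree = tree)
  ape::write.tree(tree, file.path(outDir, "tree.nwk"))

  # ---- report --------------------------------------------------------------
  fmt1 <- function(x) formatC(x, format = "f", digits = 1L)
  report <- c(
    paste0("# ", meta),
    "",
    "## Quadripartite structure (genotype / total / LSC / SSC / IR)",
    sprintf("%s\t%d\t%d\t%d\t%d", st$genotype, st$total, st$lsc, st$ssc, st$ir),
    "",
    "## SNP sites",
    sprintf("total SNP sites: %d; indel events: %d",
            nrow(variantSites(vp)), nrow(indelEvents(vp))),
    "",
    "## SNP sharing categories",
    sprintf("%s\t%d", names(cls$counts), as.integer(cls$counts)),
    "",
    "## SSR loci",
    sprintf("total SSR loci: %d (%d polymorphic)",
            nrow(ssr@loci), sum(ssr@loci$polymorphic)),
    sprintf("%s\t%d", names(table(ssrCls$category)), as.integer(table(ssrCls$category))),
    "",
    "## Bottleneck statistics",
    sprintf("%d out of %d SNPs polymorphic among cultivated genotypes (%s%%)",
            stats$snp_cultivated[["count"]], stats$snp_cultivated[["total"]],
            fmt1(stats$snp_cultivated[["fraction"]])),
    sprintf("%d out of %d SNPs polymorphic among wild genotypes (%s%%), %d-fold the cultivated count",
            stats$snp_wild[["count"]], stats$snp_wild[["total"]],
            fmt1(stats$snp_wild[["fraction"]]), stats$snp_fold),
    sprintf("cultivated genotypes share %d out of %d SNP alleles (%s%%) with pimpinellifolium",
            stats$snp_shared[["count"]], stats$snp_shared[["total"]],
            fmt1(stats$snp_shared[["fraction"]])),
    sprintf("%d out of %d SSRs polymorphic among cultivated genotypes (%s%%)",
            stats$ssr_cultivated[["count"]], stats$ssr_cultivated[["total"]],
            fmt1(stats$ssr_cultivated[["fraction"]])),
    sprintf("%d out of %d SSRs polymorphic among wild genotypes (%s%%), %d-fold the cultivated count",
            stats$ssr_wild[["count"]], stats$ssr_wild[["total"]],
            fmt1(stats$ssr_wild[["fraction"]]), stats$ssr_fold),
    sprintf("cultivated genotypes share %d out of %d SSR haplotypes (%s%%) with pimpinellifolium",
            stats$ssr_shared[["count"]], stats$ssr_shared[["total"]],
            fmt1(stats$ssr_shared[["fraction"]])),
    "",
    "## Neighbor-joining tree (bootstrap supports on internal nodes)",
    ape::write.tree(tree)
  )
  writeLines(report, file.path(outDir, "report.txt"))

  invisible(list(structures = structures, structure_table = st, variants = vp,
                 ssr = ssr, tandem_repeats = trTabs, classification = cls,
                 ssr_classification = ssrCls, stats = stats,
                 per_gene = perGene, pairwise = pw, distances = dm,
                 tree = tree, report = report, outDir = outDir))
}
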