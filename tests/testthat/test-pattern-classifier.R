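schemeToy <- groupScheme(
  groups = c(IPA6 = "var_lycopersicum", M82 = "var_lycopersicum",
             cor = "local_accessions", pds = "local_accessions",
             cer1 = "var_cerasiforme", cer2 = "var_cerasiforme",
             pim1 = "pimpinellifolium", pim2 = "pimpinellifolium",
             habro = "wild_close"),
  distantPanel = c("penn", "peru"), referenceId = "IPA6")

alleleVec <- function(...) {
  ids <- genotypeIds(schemeToy)
  out <- setNames(rep("A", length(ids)), ids)
  over <- list(...)
  for (g in names(over)) out[g] <- over[[g]]
  out
}

test_that("group states follow the REF/ALT/MIXED/MISSING definitions", {
  gs <- groupStates(alleleVec(), "A", schemeToy)
  expect_true(all(gs$states == "REF"))
  expect_identical(gs$panel_state, "REF")

  # cer1 carries the pimpinellifolium allele, cer2 the cultivated one
  gs2 <- groupStates(alleleVec(cer1 = "T", pim1 = "T", pim2 = "T"), "A", schemeToy)
  expect_identical(unname(gs2$states["var_cerasiforme"]), "MIXED")
  expect_identical(unname(gs2$states["pimpinellifolium"]), "ALT")
  expect_identical(unname(gs2$alt["pimpinellifolium"]), "T")

  # missing members are ignored; a fully missing group is MISSING
  gs3 <- groupStates(alleleVec(cer1 = NA, cer2 = NA, pim1 = NA), "A", schemeToy)
  expect_identical(unname(gs3$states["var_cerasiforme"]), "MISSING")
  expect_identical(unname(gs3$states["pimpinellifolium"]), "REF")
})

test_that("group states match a brute-force recount on random panels", {
  set.seed(53)
  ids <- genotypeIds(schemeToy)
  for (rep_ in 1:50) {
    al <- setNames(sample(c(BASES, NA), length(ids), replace = TRUE), ids)
    ref <- sample(BASES, 1)
    gs <- groupStates(al, ref, schemeToy)
    for (g in schemeToy@groupLevels) {
      members <- names(schemeToy@groups)[schemeToy@groups == g]
      a <- al[members]; a <- a[!is.na(a)]
      expected <- if (length(a) == 0) "MISSING"
        else if (length(unique(a)) > 1) "MIXED"
        else if (unique(a) == ref) "REF" else "ALT"
      expect_identical(unname(gs$states[g]), expected)
    }
  }
})

test_that("polarization returns the allele absent from the distant panel", {
  expect_identical(polarizeAllele(alleleVec(IPA6 = "C", M82 = "C", penn = "T",
                                            peru = "T", cor = "C", pds = "C",
                                            cer1 = "C", cer2 = "C", pim1 = "C",
                                            pim2 = "C", habro = "C"),
                                  c("penn", "peru")), "C")
  both <- setNames(c("C", "T", "C", "C", "C", "C", "C", "T", "T", "C", "T"),
                   genotypeIds(schemeToy))
  expect_identical(polarizeAllele(both, c("penn", "peru")), "UNPOLARIZED")
  allMissing <- alleleVec(penn = NA, peru = NA, cor = "T")
  expect_identical(polarizeAllele(allMissing, c("penn", "peru")), "UNPOLARIZED")
  expect_error(polarizeAllele(alleleVec(), character(0)), "non-empty")
})

test_that("the five mapping rows classify their defining patterns", {
  st <- function(...) c(...)
  expect_identical(
    classifyPattern(st("REF", "REF", "REF", "REF", "REF"), "ALT"),
    "lineage_ancestral")
  expect_identical(
    classifyPattern(st("REF", "REF", "REF", "REF", "ALT"), "ALT"),
    "pimpinellifolium_lineage")
  expect_identical(
    classifyPattern(st("REF", "REF", "REF", "REF", "MIXED"), "MIXED"),
    "pimpinellifolium_lineage")
  expect_identical(
    classifyPattern(st("REF", "REF", "MIXED", "ALT", "ALT"), "ALT"),
    "de_novo_cultivated")
  # a cerasiforme/pimpinellifolium-side mutation (panel REF) is not de novo
  expect_identical(
    classifyPattern(st("REF", "REF", "MIXED", "ALT", "REF"), "REF"),
    "other")
  expect_identical(
    classifyPattern(st("REF", "ALT", "MIXED", "ALT", "ALT"), "ALT",
                    alt = c(NA, "T", NA, "T", "T")),
    "commercial_lineage_specific")
  # rule 4 requires local and pimpinellifolium to share one allele
  expect_identical(
    classifyPattern(st("REF", "ALT", "MIXED", "ALT", "ALT"), "ALT",
                    alt = c(NA, "T", NA, "G", "T")),
    "other")
  expect_identical(
    classifyPattern(st("REF", "ALT", "REF", "REF", "REF"), "REF"),
    "local_diagnostic")
  expect_error(
    classifyPattern(st("REF", "REF", "REF", "REF", "REF"), "REF"),
    "not a variant")
})

test_that("classification is total and exclusive over all state vectors", {
  states <- c("REF", "ALT", "MIXED", "MISSING")
  grid <- expand.grid(V = states, L = states, C = states, P = states,
                      W = states, panel = states, stringsAsFactors = FALSE)
  cats <- variantCategories()
  for (i in seq_len(nrow(grid))) {
    v <- unlist(grid[i, 1:5])
    p <- grid$panel[i]
    if (all(v == "REF") && p == "REF") {
      expect_error(classifyPattern(v, p), "not a variant")
    } else {
      got <- classifyPattern(v, p)
      expect_true(got %in% cats)
      # deterministic
      expect_identical(classifyPattern(v, p), got)
    }
  }
})

test_that("panel strictness only widens rule 1", {
  v <- c("REF", "REF", "REF", "REF", "REF")
  expect_identical(classifyPattern(v, "MIXED"), "other")
  expect_identical(classifyPattern(v, "MIXED", strictPanel = FALSE),
                   "lineage_ancestral")
})

test_that("classifyVariants recovers planted category counts and is invariant", {
  sp <- simulatePanel(smallPanelConfig(seed = 9))
  vp <- extractVariants(sp@alignment)
  cls <- classifyVariants(vp, sp@scheme)
  expect_identical(cls$counts, sp@truth$category_counts)

  # zero variants -> all counts zero
  msa0 <- plastomeAlignment(c(a = "ACGT", b = "ACGT"), "a")
  cls0 <- classifyVariants(extractVariants(msa0), sp@scheme)
  expect_true(all(cls0$counts == 0L))

  # appending a genotype identical to the reference changes no counts
  M <- alignmentMatrix(sp@alignment)
  M2 <- rbind(M, extra = M[referenceId(sp@alignment), ])
  msa2 <- plastomeAlignment(apply(M2, 1, paste, collapse = ""),
                            referenceId(sp@alignment))
  grp2 <- c(sp@scheme@groups, extra = "var_lycopersicum")
  sch2 <- groupScheme(grp2, sp@scheme@distantPanel, sp@scheme@referenceId)
  cls2 <- classifyVariants(extractVariants(msa2), sch2)
  expect_identical(cls2$counts, cls$counts)
})

test_that("derived alleles match the planted polarity", {
  sp <- simulatePanel(smallPanelConfig(seed = 9))
  vp <- extractVariants(sp@alignment)
  cls <- classifyVariants(vp, sp@scheme)
  tru <- sp@truth$variant_truth
  # ancestral sites: panel is fixed ALT, so the derived allele is the
  # reference (cultivated) allele
  anc <- cls$classification$category == "lineage_ancestral"
  expect_true(all(cls$classification$derived_allele[anc] ==
                  variantSites(vp)$ref[anc]))
  # local-diagnostic sites: the local allele is derived
  loc <- which(cls$classification$category == "local_diagnostic")
  expect_identical(cls$classification$derived_allele[loc],
                   tru$alt[match(cls$classification$position[loc], tru$position)])
})

test_that("SSR pattern classes are recovered from repeat-count haplotypes", {
  sp <- simulatePanel(smallPanelConfig(seed = 9))
  ssr <- buildSsrLocusTable(sp@alignment)
  cls <- classifySsrPatterns(ssr, sp@scheme)
  tru <- sp@truth$ssr_truth
  o <- order(tru$start)
  expect_identical(cls$category, unname(tru$expected_category[o]))

  # trivial hand cases via a direct table
  ids <- genotypeIds(sp@scheme)
  counts <- matrix(11L, nrow = length(ids), ncol = 2,
                   dimnames = list(ids, NULL))
  counts[sp@truth$subsets$local, 2] <- 9L
  toy <- new("SsrTable",
             loci = data.frame(ref_start = c(10L, 50L), ref_end = c(20L, 60L),
                               motif = "A", unit = 1L,
                               polymorphic = c(FALSE, TRUE)),
             counts = counts, meets = counts >= 8L)
  cls2 <- classifySsrPatterns(toy, sp@scheme)
  expect_identical(cls2$category,
                   c("ancestral_shared", "group_diagnostic:local_accessions"))
})
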