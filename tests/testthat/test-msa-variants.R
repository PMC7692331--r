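test_that("column mapping is the identity on gapless alignments", {
  msa <- plastomeAlignment(c(ref = "ACGTACGTAC", g2 = "ACGTACGTAC"), "ref")
  mp <- mapColumns(msa)
  expect_identical(mp$ref_position, 1:10)
  expect_false(any(mp$is_insertion))
})

test_that("column mapping matches a per-column recount with reference gaps", {
  set.seed(7)
  for (rep_ in 1:5) {
    n <- 60L
    ref <- sample(c(BASES, "-"), n, replace = TRUE, prob = c(rep(0.22, 4), 0.12))
    other <- sample(BASES, n, replace = TRUE)
    msa <- plastomeAlignment(c(ref = paste(ref, collapse = ""),
                               g2 = paste(other, collapse = "")), "ref")
    mp <- mapColumns(msa)
    # oracle: cumulative count of non-gap reference characters
    expect_identical(mp$ref_position, cumsum(ref != "-"))
    expect_identical(mp$is_insertion, ref == "-")
    expect_true(all(diff(mp$ref_position) >= 0L))
  }
})

test_that("a deletion in a non-reference row leaves the mapping unchanged", {
  msa1 <- plastomeAlignment(c(ref = "ACGTACGT", g2 = "ACGTACGT"), "ref")
  msa2 <- plastomeAlignment(c(ref = "ACGTACGT", g2 = "ACG-ACGT"), "ref")
  expect_identical(mapColumns(msa1)$ref_position, mapColumns(msa2)$ref_position)
})

test_that("identical rows yield no variants and no indels", {
  msa <- plastomeAlignment(c(ref = "ACGTACGTAC", g2 = "ACGTACGTAC"), "ref")
  vp <- extractVariants(msa)
  expect_identical(nrow(variantSites(vp)), 0L)
  expect_identical(nrow(indelEvents(vp)), 0L)
})

test_that("planted substitutions and a deletion are recovered at their positions", {
  #              123456789012345678
  rows <- c(ref = "ACGTACGTACGTACGTAC",
            g2  = "ACTTACGTACGTACGAAC",   # subs at 3, 16
            g3  = "ACGTACGTTCGTACGTAC",   # sub at 9
            g4  = "ACGTA-GTACGTACCTAG")   # del at 6, subs at 15, 18
  vp <- extractVariants(plastomeAlignment(rows, "ref"))
  expect_identical(variantSites(vp)$position, c(3L, 9L, 15L, 16L, 18L))
  expect_identical(nrow(indelEvents(vp)), 1L)
  expect_identical(indelEvents(vp)$kind, "deletion")
  expect_identical(indelEvents(vp)$position, 5L)   # base before the event
  expect_identical(indelEvents(vp)$genotypes, "g4")
  am <- alleleMatrix(vp)
  expect_identical(unname(am["g2", 1]), "T")
  # the deleted column is an indel, not a SNP site
  expect_false(6L %in% variantSites(vp)$position)
})

test_that("N and gaps are missing alleles: never creating nor suppressing a SNP", {
  # N opposite a real difference does not suppress the site
  vp <- extractVariants(plastomeAlignment(
    c(ref = "ACGT", g2 = "ANGT", g3 = "AGGT"), "ref"))
  expect_identical(variantSites(vp)$position, 2L)
  expect_true(is.na(alleleMatrix(vp)["g2", 1]))
  # a column variable only through N/- is not a SNP
  vp2 <- extractVariants(plastomeAlignment(
    c(ref = "ACGT", g2 = "ANGT", g3 = "A-GT"), "ref"))
  expect_identical(nrow(variantSites(vp2)), 0L)
})

test_that("the misalignment guard rejects absurd reference gap runs", {
  rows <- c(ref = "AC--------", g2 = "ACGTACGTAC")
  expect_error(extractVariants(plastomeAlignment(rows, "ref")),
               "misalignment guard")
})

test_that("a single point mutation inside rpoC1 exon 2 is annotated as such", {
  df <- data.frame(feature_id = "cds:rpoC1", gene = "rpoC1", kind = "CDS",
                   start = c(31L, 61L), end = c(45L, 75L), strand = "-",
                   phase = 0L, exon_rank = c(2L, 1L))
  ann <- plastomeAnnotation(df, 100L)
  ref <- randSeq(100, seed = 5)
  alt <- ref
  substr(alt, 40, 40) <- if (substr(ref, 40, 40) == "A") "C" else "A"
  vp <- extractVariants(plastomeAlignment(c(IPA6 = ref, cor = alt), "IPA6"),
                        ann = ann, refGenome = ref)
  expect_identical(nrow(variantSites(vp)), 1L)
  expect_identical(variantSites(vp)$context, "CDS:rpoC1")
})

test_that("third-position degeneracy gives a synonymous call", {
  # gene g: ATG GCT TAA at positions 11..19 (+ strand)
  ref <- paste0(strrep("C", 10), "ATGGCTTAA", strrep("G", 10))
  alt <- ref
  substr(alt, 16, 16) <- "C"   # GCT -> GCC (Ala -> Ala)
  df <- data.frame(feature_id = "cds:g", gene = "g", kind = "CDS",
                   start = 11L, end = 19L, strand = "+", phase = 0L,
                   exon_rank = 1L)
  ann <- plastomeAnnotation(df, nchar(ref))
  vp <- extractVariants(plastomeAlignment(c(ref = ref, g2 = alt), "ref"),
                        ann = ann, refGenome = ref)
  expect_identical(variantSites(vp)$effect, "synonymous")
})

test_that("a minus-strand first-position change is nonsynonymous (Met -> Val)", {
  # minus-strand CDS CAT|TTT|CAT -> revcomp ATG AAA ATG; change genomic CAT
  # to CAC so the first codon reads GTG (Val)
  ref <- paste0(strrep("G", 5), "CATTTTCAT", strrep("C", 5))
  alt <- ref
  substr(alt, 14, 14) <- "C"   # last CAT -> CAC; rc: ATG -> GTG
  df <- data.frame(feature_id = "cds:m", gene = "m", kind = "CDS",
                   start = 6L, end = 14L, strand = "-", phase = 0L,
                   exon_rank = 1L)
  ann <- plastomeAnnotation(df, nchar(ref))
  vp <- extractVariants(plastomeAlignment(c(ref = ref, g2 = alt), "ref"),
                        ann = ann, refGenome = ref)
  expect_identical(variantSites(vp)$effect, "nonsynonymous")
  expect_identical(variantSites(vp)$aa_change, "M1V")
})

test_that("coding effects agree with whole-protein translation on random CDS SNPs", {
  set.seed(99)
  code <- Biostrings::getGeneticCode("11")
  for (rep_ in 1:100) {
    strand <- sample(c("+", "-"), 1)
    nCodon <- sample(5:30, 1)
    gs <- 21L
    ge <- gs + nCodon * 3L - 1L
    ref <- randSeq(ge + 20L)
    df <- data.frame(feature_id = "cds:g", gene = "g", kind = "CDS",
                     start = gs, end = ge, strand = strand, phase = 0L,
                     exon_rank = 1L)
    ann <- plastomeAnnotation(df, nchar(ref))
    p <- sample(gs:ge, 1)
    altBase <- sample(setdiff(BASES, substr(ref, p, p)), 1)
    alt <- ref
    substr(alt, p, p) <- altBase
    # oracle: translate the whole CDS of both sequences independently
    cds <- function(s) {
      x <- substr(s, gs, ge)
      if (strand == "-") x <- revcompStr(x)
      # plain codon-table translation (no initiator special-casing), matching
      # the per-codon semantics of the effect caller
      as.character(Biostrings::translate(Biostrings::DNAString(x),
                                         genetic.code = code,
                                         no.init.codon = TRUE))
    }
    aaRef <- cds(ref); aaAlt <- cds(alt)
    expEffect <- if (identical(aaRef, aaAlt)) "synonymous" else "nonsynonymous"
    vp <- extractVariants(plastomeAlignment(c(ref = ref, g2 = alt), "ref"),
                          ann = ann, refGenome = ref)
    expect_identical(variantSites(vp)$effect, expEffect)
  }
})

test_that("tandem-duplication insertions are recognized against both flanks", {
  ev <- list(position = 8, kind = "insertion", length = 4, bases = "ATAA")
  expect_true(classifyIndelDuplication(ev, "GGGGATAACCCC"))   # left flank
  ev2 <- list(position = 4, kind = "insertion", length = 4, bases = "ATAA")
  expect_true(classifyIndelDuplication(ev2, "GGGGATAACCCC"))  # right flank
  ev3 <- list(position = 8, kind = "insertion", length = 4, bases = "GGGG")
  expect_false(classifyIndelDuplication(ev3, "GGGGATAACCCC"))
  # random insertions agree with a direct string comparison
  set.seed(13)
  for (rep_ in 1:20) {
    s <- randSeq(60)
    len <- sample(1:5, 1)
    p <- sample(seq(len + 1, 60 - len), 1)
    ins <- if (runif(1) < 0.5) substr(s, p - len + 1, p) else randSeq(len)
    ev <- list(position = p, kind = "insertion", length = len, bases = ins)
    expected <- identical(ins, substr(s, p - len + 1, p)) ||
      identical(ins, substr(s, p + 1, p + len))
    expect_identical(classifyIndelDuplication(ev, s), expected)
  }
})

test_that("context counts per genotype sum to pairwise SNP counts", {
  sp <- simulatePanel(smallPanelConfig(seed = 5))
  vp <- extractVariants(sp@alignment, ann = sp@annotation,
                        structure = sp@structure)
  ctx <- countByContext(vp)
  pw <- pairwiseCountsVsReference(vp)
  expect_identical(setNames(ctx$total, ctx$genotype), pw)
  expect_identical(unname(pw[referenceId(sp@alignment)]), 0L)
  expect_identical(unname(pw), unname(sp@truth$pairwise_truth[names(pw)]))
})

test_that("VCF export writes one record per site with GT columns", {
  rows <- c(ref = "ACGTACGTAC", g2 = "ACCTACGTAC", g3 = "ACGTACNTAT")
  vp <- extractVariants(plastomeAlignment(rows, "ref"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVariantsVcf(vp, f, contigLength = 10L)
  lines <- readLines(f)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), nrow(variantSites(vp)))
  hdr <- lines[startsWith(lines, "#CHROM")]
  expect_match(hdr, "FORMAT\tref\tg2\tg3")
  fields <- strsplit(body[1], "\t")[[1]]
  expect_identical(length(fields), 12L)   # 9 fixed + 3 genotypes
})
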