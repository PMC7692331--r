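test_that("FASTA reading normalizes case and RNA, and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "acgu", ">g2", "ACGTN"), f)
  seqs <- readPlastomes(f)
  expect_identical(names(seqs), c("g1", "g2"))
  expect_identical(as.character(seqs[["g1"]]), "ACGT")
  expect_identical(as.character(seqs[["g2"]]), "ACGTN")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writePlastomes(seqs, f2, width = 2L)
  again <- readPlastomes(f2)
  expect_identical(as.character(again), as.character(seqs))
})

test_that("a full-length plastome record reads at its exact size", {
  f <- withr::local_tempfile(fileext = ".fasta")
  n <- 155435L
  writeLines(c(">cor", strrep("ACGT", n %/% 4), substr("ACGT", 1, n %% 4)), f)
  seqs <- readPlastomes(f)
  expect_identical(Biostrings::width(seqs)[[1]], n)
})

test_that("FASTA reading rejects duplicates, empties and bad characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(readPlastomes(f), "duplicate.*a")
  writeLines(c(">a", "ACGT", ">b", ""), f)
  expect_error(readPlastomes(f), "empty record")
  writeLines(c(">a", "ACXT"), f)
  expect_error(readPlastomes(f), "invalid characters")
})

test_that("GFF3 reading joins spliced CDS and enforces frame invariants", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr 1 1000",
    "chr\t.\tgene\t5\t200\t.\t+\t.\tID=gene:gA;Name=gA",
    "chr\t.\tCDS\t10\t18\t.\t+\t0\tID=cds:gA;Parent=gene:gA",
    "chr\t.\tgene\t300\t701\t.\t-\t.\tID=gene:rpoC1;Name=rpoC1",
    "chr\t.\tCDS\t300\t449\t.\t-\t0\tID=cds:rpoC1;Parent=gene:rpoC1",
    "chr\t.\tCDS\t600\t701\t.\t-\t0\tID=cds:rpoC1;Parent=gene:rpoC1"
  ), f)
  ann <- readAnnotationGff(f)
  gr <- annotationFeatures(ann)
  m <- S4Vectors::mcols(gr)
  one <- gr[m$feature_id == "cds:gA" & m$kind == "CDS"]
  expect_identical(GenomicRanges::end(one) - GenomicRanges::start(one) + 1L, 9L)
  spliced <- gr[m$feature_id == "cds:rpoC1" & m$kind == "CDS"]
  expect_length(spliced, 2L)
  # minus strand: translation rank 1 is the rightmost interval
  rk <- S4Vectors::mcols(spliced)$exon_rank[order(GenomicRanges::start(spliced))]
  expect_identical(rk, c(2L, 1L))
  # a position inside exon 2 (the left interval) is CDS:rpoC1
  expect_identical(contextOf(350L, ann), "CDS:rpoC1")
})

test_that("CDS length not divisible by three warns and flags non-translatable", {
  df <- data.frame(feature_id = "cds:bad", gene = "bad", kind = "CDS",
                   start = 10L, end = 20L, strand = "+", phase = 0L,
                   exon_rank = 1L)
  expect_warning(ann <- plastomeAnnotation(df, 100L), "non-translatable")
  m <- S4Vectors::mcols(annotationFeatures(ann))
  expect_false(any(m$translatable[m$kind == "CDS"]))
})

test_that("contextOf handles the CDS / intron / intergenic cases", {
  df <- rbind(
    data.frame(feature_id = "cds:g1", gene = "g1", kind = "CDS",
               start = c(50L, 80L), end = c(70L, 100L), strand = "+",
               phase = 0L, exon_rank = 1:2),
    data.frame(feature_id = "trna:g2", gene = "g2", kind = "tRNA",
               start = 200L, end = 260L, strand = "+", phase = 0L, exon_rank = 1L)
  )
  ann <- plastomeAnnotation(df, 1000L)
  expect_identical(contextOf(60L, ann), "CDS:g1")
  expect_identical(contextOf(75L, ann), "intron:g1")   # inside span, between exons
  expect_identical(contextOf(150L, ann), "intergenic:g1-g2")
  expect_identical(contextOf(230L, ann), "CDS:g2")     # tRNA exon counts as coding
  expect_identical(contextOf(500L, ann), "intergenic:g2-g1")  # circular wrap
  expect_error(contextOf(0L, ann), "out of range")
  expect_error(contextOf(1001L, ann), "out of range")
})

test_that("contextOf partitions the genome and matches the interval-scan oracle", {
  set.seed(42)
  n <- 3000L
  for (rep_ in 1:4) {
    # random non-overlapping genes, some spliced
    nGene <- 6L
    bounds <- sort(sample(seq(10L, n - 10L, by = 15L), 2L * nGene))
    rows <- list()
    for (k in seq_len(nGene)) {
      s <- bounds[2L * k - 1L]; e <- bounds[2L * k]
      if (e - s > 20L && runif(1) < 0.5) {
        m1 <- s + (e - s) %/% 3L
        m2 <- e - (e - s) %/% 3L
        rows[[k]] <- data.frame(feature_id = paste0("f", k), gene = paste0("g", k),
                                kind = "tRNA", start = c(s, m2), end = c(m1, e),
                                strand = "+", phase = 0L, exon_rank = 1:2)
      } else {
        rows[[k]] <- data.frame(feature_id = paste0("f", k), gene = paste0("g", k),
                                kind = "tRNA", start = s, end = e,
                                strand = "+", phase = 0L, exon_rank = 1L)
      }
    }
    df <- do.call(rbind, rows)
    ann <- plastomeAnnotation(df, n)
    pos <- seq_len(n)
    got <- contextOf(pos, ann)
    cls <- sub(":.*", "", got)
    expect_identical(sum(table(cls)), as.integer(n))  # partition of [1, n]
    expect_identical(got, contextOracle(pos, df, n))
  }
})

test_that("group scheme files round-trip", {
  sch <- groupScheme(
    groups = c(r = "var_lycopersicum", l1 = "local_accessions",
               c1 = "var_cerasiforme", p1 = "pimpinellifolium",
               w1 = "wild_close"),
    distantPanel = c("d1", "d2"), referenceId = "r")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGroupScheme(sch, f)
  sch2 <- readGroupScheme(f)
  expect_identical(sch2@groups, sch@groups)
  expect_identical(sch2@distantPanel, sch@distantPanel)
  expect_identical(sch2@referenceId, sch@referenceId)
})

test_that("GroupScheme validity catches malformed schemes", {
  expect_error(groupScheme(c(a = "var_lycopersicum"), character(0), "a"),
               "non-empty")
  expect_error(groupScheme(
    c(a = "var_lycopersicum", b = "local_accessions", c = "var_cerasiforme",
      d = "pimpinellifolium", e = "wild_close"),
    distantPanel = "a", referenceId = "a"), "disjoint")
})
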