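test_that("mono-nucleotide threshold boundary is exact (7xA vs 8xA)", {
  hit <- findSSRs(paste0("GCGTC", strrep("A", 8), "TCGGC"), circular = FALSE)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$motif, "A")
  expect_identical(hit$units, 8L)
  miss <- findSSRs(paste0("GCGTC", strrep("A", 7), "TCGGC"), circular = FALSE)
  expect_identical(nrow(miss), 0L)
})

test_that("a planted (AT)6 is found as exactly one dinucleotide locus", {
  set.seed(17)
  repeat {
    s <- randSeq(1000)
    if (nrow(findSSRs(s, circular = FALSE)) == 0L) break
  }
  s2 <- paste0(substr(s, 1, 500), "G", strrep("AT", 6), "CC", substr(s, 501, 1000))
  hits <- findSSRs(s2, circular = FALSE)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$canonical, "AT")
  expect_identical(hits$units, 6L)
})

test_that("canonical motifs are minimal rotations of the primitive root", {
  expect_identical(canonicalMotif("TA"), "AT")
  expect_identical(canonicalMotif("AGA"), "AAG")
  expect_identical(canonicalMotif("ATAT"), "AT")   # non-primitive root reduced
  # strands stay distinct: TA and its reverse complement both canonicalize
  # within their own rotation class
  expect_identical(canonicalMotif("GT"), "GT")
  expect_identical(canonicalMotif("AC"), "AC")
  # enumeration oracle over all trinucleotide motifs
  rotMin <- function(m) {
    v <- strsplit(m, "")[[1]]
    min(vapply(seq_along(v), function(r)
      paste(v[c(r:length(v), seq_len(r - 1))[seq_along(v)]], collapse = ""),
      character(1)))
  }
  for (m in apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")) {
    v <- strsplit(m, "")[[1]]
    prim <- !(v[1] == v[2] && v[2] == v[3])
    expected <- if (prim) rotMin(m) else v[1]
    expect_identical(canonicalMotif(m), expected)
  }
})

test_that("SSR detection agrees with the brute-force scanner on random toys", {
  set.seed(23)
  for (rep_ in 1:20) {
    v <- sample(c(BASES, BASES, "A", "T"), 2000, replace = TRUE)
    # salt with repeat-like stretches so hits actually occur
    for (k in 1:4) {
      u <- sample(1:4, 1)
      units <- sample(4:10, 1)
      motif <- paste(sample(BASES, u, replace = TRUE), collapse = "")
      p <- sample(seq_len(2000 - u * units), 1)
      v[p:(p + u * units - 1)] <- strsplit(strrep(motif, units), "")[[1]]
    }
    s <- paste(v, collapse = "")
    got <- findSSRs(s, circular = FALSE)[, c("start", "end", "unit", "units")]
    exp <- ssrOracle(s)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got, exp)
  }
})

test_that("perfect tandem repeats are found with period and copy number", {
  unit <- "ACGTTGCAGGCTA"            # 13 bp primitive
  s <- paste0("GGCCTT", strrep(unit, 2), "TTGGAA")
  tr <- findTandemRepeats(s, circular = FALSE)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$period, 13L)
  expect_identical(tr$copy_number, 2)
  expect_identical(tr$total_length, 26L)
})

test_that("random sequence without long duplications has no tandem repeats", {
  set.seed(31)
  repeat {
    s <- randSeq(2000)
    if (nrow(trOracle(s)) == 0L) break
  }
  expect_identical(nrow(findTandemRepeats(s, circular = FALSE)), 0L)
})

test_that("tandem repeat detection agrees with the all-(start, period) oracle", {
  set.seed(37)
  for (rep_ in 1:5) {
    v <- sample(BASES, 2000, replace = TRUE)
    for (k in 1:3) {
      p <- sample(13:26, 1)
      copies <- sample(2:3, 1)
      unit <- randSeq(p)
      at <- sample(seq_len(2000 - p * copies), 1)
      v[at:(at + p * copies - 1)] <- strsplit(strrep(unit, copies), "")[[1]]
    }
    s <- paste(v, collapse = "")
    got <- findTandemRepeats(s, circular = FALSE)[, c("start", "end", "period",
                                                      "copy_number", "total_length")]
    exp <- trOracle(s)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got, exp)
  }
})

test_that("arrays periodic at a multiple of a qualifying period report once", {
  unit <- "ACGTTGCAGGCTA"
  s <- paste0("GG", strrep(unit, 4), "TT")   # period 13 x 4 == period 26 x 2
  tr <- findTandemRepeats(s, circular = FALSE)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$period, 13L)
})

test_that("SSR locus counts are strand-symmetric", {
  set.seed(41)
  v <- sample(c(BASES, "A", "T"), 1500, replace = TRUE)
  v[100:111] <- rep(c("A", "T"), 6)
  v[700:709] <- rep("A", 10)
  s <- paste(v, collapse = "")
  fwd <- findSSRs(s, circular = FALSE)
  rev_ <- findSSRs(revcompStr(s), circular = FALSE)
  expect_identical(nrow(fwd), nrow(rev_))
  expect_identical(sort(fwd$length), sort(rev_$length))
})

test_that("every reported repeat interval re-reads as a perfect repeat", {
  sp <- simulatePanel(smallPanelConfig(seed = 9))
  s <- as.character(sp@sequences[[1]])
  v <- strsplit(s, "")[[1]]
  ssrs <- findSSRs(s, circular = FALSE)
  for (i in seq_len(nrow(ssrs))) {
    span <- v[ssrs$start[i]:ssrs$end[i]]
    u <- ssrs$unit[i]
    expect_true(all(span[seq_len(length(span) - u)] ==
                    span[seq_len(length(span) - u) + u]))
  }
  trs <- findTandemRepeats(s, circular = FALSE)
  for (i in seq_len(nrow(trs))) {
    span <- v[trs$start[i]:trs$end[i]]
    p <- trs$period[i]
    expect_true(all(span[seq_len(length(span) - p)] ==
                    span[seq_len(length(span) - p) + p]))
  }
})

test_that("the cross-genotype SSR table recovers planted counts exactly", {
  sp <- simulatePanel(smallPanelConfig(seed = 9))
  ssr <- buildSsrLocusTable(sp@alignment)
  tru <- sp@truth$ssr_truth
  o <- order(tru$start)
  expect_identical(nrow(ssr@loci), nrow(tru))
  expect_identical(ssr@loci$ref_start, tru$start[o])
  expect_identical(ssr@loci$motif, vapply(tru$motif[o], canonicalMotif, character(1),
                                          USE.NAMES = FALSE))
  expect_identical(unname(ssr@counts), unname(sp@truth$ssr_counts[, o]))
  expect_identical(unname(ssr@loci$polymorphic), unname(tru$polymorphic[o]))
  # genotypes below threshold are still recounted at the locus
  expect_true(any(!ssr@meets & !is.na(ssr@counts)))
})

test_that("mono-nucleotide loci dominate on the default-style genome", {
  sp <- simulatePanel(smallPanelConfig(seed = 9))
  ssr <- buildSsrLocusTable(sp@alignment)
  tab <- table(ssr@loci$unit)
  expect_true(tab[["1"]] > max(tab[names(tab) != "1"]))
})
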