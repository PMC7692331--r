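#' Simulate a plastome panel with planted, classified variation
#'
#' Generates the reference genome ([generateReference()]), then plants every
#' blueprint site pattern, SSR repeat-count haplotype, tandem repeat and
#' indel on a 21-genotype panel (defaults), emitting a gap-consistent true
#' alignment, ungapped per-genotype sequences and truth tables. Mutation
#' patterns are consistent with a fixed species tree (distant clade;
#' wild-close genotypes basal to the cultivated side; cer1 attached next to
#' the pimpinellifolium pair; cer2 inside the cultivated clade), so the
#' sharing categories are edge-based and recoverable.
#'
#' @param config a [simulationConfig()].
#' @return a [SimulatedPanel-class].
#' @export
simulatePanel <- function(config = simulationConfig()) {
  ref <- generateReference(config)
  roster <- .simRoster(config)
  scheme <- roster$scheme
  ids <- roster$ids
  nG <- length(ids)
  v <- .toVec(ref$sequence)
  n <- length(v)
  nL <- config$lsc_length; nI <- config$ir_length

  counts <- c(config$category_counts, config$other_counts)
  if (counts[["m82_private"]] > 0L)
    .check(length(roster$vlyc) >= 2L,
           "m82_private sites need a second var_lycopersicum genotype")
  carrierSets <- .simCarrierSets(roster)
  subtypeCategory <- c(
    lineage_ancestral = "lineage_ancestral",
    pimpinellifolium_lineage = "pimpinellifolium_lineage",
    de_novo_cultivated = "de_novo_cultivated",
    commercial_lineage_specific = "commercial_lineage_specific",
    local_diagnostic = "local_diagnostic",
    m82_private = "other", cor_private = "other", cer2_private = "other",
    pim1_private = "other", pim2_private = "other", pim_pair = "other",
    cer1_pim_clade = "other", wild_shared = "other"
  )

  # ---- exclusion masks -----------------------------------------------------
  excl <- rep(FALSE, n)
  excl[seq.int(nL + 1L, nL + nI)] <- TRUE                       # IRa
  excl[seq.int(n - nI + 1L, n)] <- TRUE                         # IRb
  maskIv <- function(s, e, pad = 0L) {
    excl[max(1L, s - pad):min(n, e + pad)] <<- TRUE
  }
  for (i in seq_len(nrow(ref$ssr))) maskIv(ref$ssr$start[i], ref$ssr$end[i], 6L)
  for (i in seq_len(nrow(ref$tr))) maskIv(ref$tr$start[i], ref$tr$end[i], 6L)
  chosenMask <- rep(FALSE, n)

  geneIv <- function(g, rank = NULL) {
    gr <- ref$annotation@features
    m <- mcols(gr)
    sel <- m$gene == g & m$kind %in% c("CDS", "tRNA", "rRNA")
    if (!is.null(rank)) sel <- sel & m$exon_rank == rank
    c(min(start(gr)[sel]), max(end(gr)[sel]))
  }

  # ---- indel placement (before SNP placement) ------------------------------
  bases <- c("A", "C", "G", "T")
  windowClean <- function(p, pad = 8L) {
    w <- v[max(1L, p - pad):min(n, p + pad)]
    max(rle(w)$lengths) <= 3L
  }
  pglPos <- NA_integer_
  if (config$pgl_deletion && length(roster$loc) >= 3L) {
    cand <- sample(which(!excl))
    for (p in cand) {
      if (p > 2L && p < n - 1L && v[p - 1L] != v[p + 1L] && windowClean(p)) {
        pglPos <- p; break
      }
    }
    .check(!is.na(pglPos), "no eligible position for the 1-bp deletion")
    chosenMask[max(1L, pglPos - 3L):min(n, pglPos + 3L)] <- TRUE
  }
  ataaAnchor <- NA_integer_
  if (config$ataa_duplication) {
    occ <- which(v[seq_len(n - 3L)] == "A" & v[seq_len(n - 3L) + 1L] == "T" &
                 v[seq_len(n - 3L) + 2L] == "A" & v[seq_len(n - 3L) + 3L] == "A")
    occ <- occ[occ > 12L & occ < nL - 12L]                      # LSC interior
    for (p0 in occ) {
      win <- seq.int(p0 - 8L, p0 + 11L)
      if (!any(excl[win]) && !any(chosenMask[win]) && windowClean(p0 + 1L, 10L)) {
        ataaAnchor <- p0 + 3L                                   # insert after this base
        break
      }
    }
    .check(!is.na(ataaAnchor), "no eligible ATAA source site found")
    chosenMask[(ataaAnchor - 6L):(ataaAnchor + 6L)] <- TRUE
  }

  # ---- SNP site placement --------------------------------------------------
  remaining <- counts
  sites <- list()
  code <- Biostrings::getGeneticCode("11")
  altAt <- function(p) {
    .simPickBase(v[p], c(v[max(1L, p - 1L)], v[min(n, p + 1L)],
                         v[max(1L, p - 2L)], v[min(n, p + 2L)]))
  }
  takePos <- function(p) {
    chosenMask[max(1L, p - 3L):min(n, p + 3L)] <<- TRUE
  }
  addSite <- function(p, subtype, alt) {
    sites[[length(sites) + 1L]] <<- data.frame(
      position = p, subtype = subtype, category = subtypeCategory[[subtype]],
      ref = v[p], alt = alt, stringsAsFactors = FALSE)
    takePos(p)
  }
  eligible <- function(p) !excl[p] && !chosenMask[p]

  # ndhH: synonymous sites at third positions of fourfold-degenerate codons
  fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  q <- min(9L, remaining[["lineage_ancestral"]])
  if (q > 0L) {
    iv <- geneIv("ndhH")
    cs <- seq.int(iv[1L], iv[2L] - 2L, by = 3L)
    ok <- paste0(v[cs], v[cs + 1L]) %in% fourfold
    third <- (cs + 2L)[ok]
    third <- third[vapply(third, eligible, logical(1))]
    .check(length(third) >= q, "too few fourfold-degenerate ndhH codons")
    third <- third[sample.int(length(third), q)]
    for (p in third) addSite(p, "lineage_ancestral", altAt(p))
    remaining[["lineage_ancestral"]] <- remaining[["lineage_ancestral"]] - q
  }

  # ycf1: one nonsynonymous local-diagnostic site plus a category mix
  ivY <- geneIv("ycf1")
  if (remaining[["local_diagnostic"]] > 0L) {
    csAll <- seq.int(ivY[1L], ivY[2L] - 2L, by = 3L)
    csY <- csAll[sample.int(length(csAll))]
    placed <- FALSE
    for (cs in csY) {
      p <- cs + 1L
      if (!eligible(p)) next
      codon <- .fromVec(v[cs:(cs + 2L)])
      aaRef <- code[[codon]]
      if (aaRef == "*") next
      for (alt in setdiff(bases, v[p])) {
        codonAlt <- v[cs:(cs + 2L)]; codonAlt[2L] <- alt
        aaAlt <- code[[.fromVec(codonAlt)]]
        if (aaAlt != aaRef && aaAlt != "*") {
          addSite(p, "local_diagnostic", alt)
          remaining[["local_diagnostic"]] <- remaining[["local_diagnostic"]] - 1L
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
  }
  ycf1Quota <- c(lineage_ancestral = 25L, pimpinellifolium_lineage = 10L,
                 de_novo_cultivated = 6L)
  for (sub in names(ycf1Quota)) {
    q <- min(ycf1Quota[[sub]], remaining[[sub]])
    if (q == 0L) next
    pool <- seq.int(ivY[1L], ivY[2L])
    pool <- pool[vapply(pool, eligible, logical(1))]
    pool <- pool[sample.int(length(pool))]
    got <- 0L
    for (p in pool) {
      if (!eligible(p)) next
      addSite(p, sub, altAt(p))
      got <- got + 1L
      if (got == q) break
    }
    remaining[[sub]] <- remaining[[sub]] - got
  }

  # matK carries one commercial-lineage site; rpoC1 exon 2 the cor-private one
  placeOne <- function(gene, sub, rank = NULL) {
    if (remaining[[sub]] == 0L) return(invisible(NULL))
    iv <- geneIv(gene, rank)
    pool <- seq.int(iv[1L], iv[2L])
    pool <- pool[sample.int(length(pool))]
    for (p in pool) {
      if (eligible(p)) {
        addSite(p, sub, altAt(p))
        remaining[[sub]] <<- remaining[[sub]] - 1L
        return(invisible(NULL))
      }
    }
  }
  placeOne("matK", "commercial_lineage_specific")
  placeOne("rpoC1", "cor_private", rank = 2L)

  # everything else goes anywhere in the single-copy regions outside the
  # most-variable genes (their per-gene counts stay exactly as planted)
  maskIv(ivY[1L], ivY[2L])
  ivN <- geneIv("ndhH"); maskIv(ivN[1L], ivN[2L])
  genPool <- sample(which(!excl & !chosenMask))
  gi <- 0L
  for (sub in names(remaining)) {
    need <- remaining[[sub]]
    while (need > 0L) {
      gi <- gi + 1L
      .check(gi <= length(genPool), "ran out of eligible SNP positions")
      p <- genPool[gi]
      if (!eligible(p) || p <= 2L || p >= n - 1L) next
      addSite(p, sub, altAt(p))
      need <- need - 1L
    }
    remaining[[sub]] <- 0L
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(position = integer(), subtype = character(),
               category = character(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites$carriers <- vapply(sites$subtype, function(s)
    paste(carrierSets[[s]], collapse = ","), character(1), USE.NAMES = FALSE)

  # ---- assemble the true alignment ----------------------------------------
  M <- matrix(v, nrow = nG, ncol = n, byrow = TRUE, dimnames = list(ids, NULL))
  for (i in seq_len(nrow(sites))) {
    M[carrierSets[[sites$subtype[i]]], sites$position[i]] <- sites$alt[i]
  }
  ssrCounts <- .simSsrCounts(ref$ssr, roster)
  for (li in seq_len(nrow(ref$ssr))) {
    kRef <- ref$ssr$ref_units[li]
    u <- ref$ssr$unit[li]
    for (g in ids) {
      d <- kRef - ssrCounts[g, li]
      if (d > 0L) {
        cols <- seq.int(ref$ssr$end[li] - d * u + 1L, ref$ssr$end[li])
        M[g, cols] <- "-"
      }
    }
  }
  indelTruth <- list()
  if (!is.na(pglPos)) {
    M[roster$loc[3L], pglPos] <- "-"
    indelTruth[[length(indelTruth) + 1L]] <- data.frame(
      kind = "deletion", position = pglPos - 1L, length = 1L,
      bases = v[pglPos], genotypes = roster$loc[3L],
      is_tandem_duplication = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.na(ataaAnchor)) {
    block <- matrix("-", nG, 4L, dimnames = list(ids, NULL))
    block[roster$loc, ] <- matrix(rep(c("A", "T", "A", "A"), each = length(roster$loc)),
                                  nrow = length(roster$loc))
    M <- cbind(M[, seq_len(ataaAnchor), drop = FALSE], block,
               M[, seq.int(ataaAnchor + 1L, n), drop = FALSE])
    indelTruth[[length(indelTruth) + 1L]] <- data.frame(
      kind = "insertion", position = ataaAnchor, length = 4L,
      bases = "ATAA", genotypes = paste(sort(roster$loc), collapse = ","),
      is_tandem_duplication = TRUE, stringsAsFactors = FALSE)
  }
  indelTruth <- if (length(indelTruth)) do.call(rbind, indelTruth) else
    data.frame(kind = character(), position = integer(), length = integer(),
               bases = character(), genotypes = character(),
               is_tandem_duplication = logical())

  rows <- apply(M, 1L, paste, collapse = "")
  aln <- plastomeAlignment(rows, roster$vlyc[1L])
  seqs <- DNAStringSet(vapply(rows, function(r) gsub("-", "", r, fixed = TRUE),
                              character(1)))
  names(seqs) <- ids

  # ---- truth tables (computed from the blueprint, not hard-coded) ----------
  carrierM <- matrix(FALSE, nG, nrow(sites), dimnames = list(ids, NULL))
  for (i in seq_len(nrow(sites)))
    carrierM[carrierSets[[sites$subtype[i]]], i] <- TRUE
  cultivated <- c(roster$vlyc, roster$loc, roster$cer[2L])
  wildSubset <- c(roster$pim, roster$wild, roster$dist)
  polyIn <- function(mat, subset) {
    sub <- mat[subset, , drop = FALSE]
    sum(apply(sub, 2L, function(x) length(unique(x[!is.na(x)])) >= 2L))
  }
  sharedIn <- function(mat, a, b) {
    sub <- mat[c(a, b), , drop = FALSE]
    sum(apply(sub, 2L, function(x) length(unique(x[!is.na(x)])) == 1L))
  }
  classMap <- c(ancestral = "ancestral_shared",
                lineage_shared = "lineage_pattern",
                local_diagnostic = "group_diagnostic:local_accessions",
                vlyc_diagnostic = "group_diagnostic:var_lycopersicum",
                cer2_mixed = "other", m82_mixed = "other", pim_shift = "other")
  ssrTruth <- ref$ssr
  ssrTruth$expected_category <- classMap[ssrTruth$class]
  # pim_shift loci where cer1 keeps the reference count leave the
  # pimpinellifolium pair alone at a count nobody else has
  cer1 <- roster$cer[1L]
  shift <- which(ssrTruth$class == "pim_shift")
  pimOnly <- shift[ssrCounts[cer1, shift] == ssrTruth$ref_units[shift]]
  ssrTruth$expected_category[pimOnly] <- "group_diagnostic:pimpinellifolium"
  ssrTruth$polymorphic <- apply(ssrCounts, 2L, function(x) length(unique(x)) >= 2L)

  catCounts <- setNames(integer(length(variantCategories())), variantCategories())
  tb <- table(sites$category)
  catCounts[names(tb)] <- as.integer(tb)

  truth <- list(
    variant_truth = sites,
    category_counts = catCounts,
    snp_stats = list(
      total = nrow(sites),
      cultivated_polymorphic = polyIn(carrierM, cultivated),
      wild_polymorphic = polyIn(carrierM, wildSubset),
      shared_with_pim = sharedIn(carrierM, cultivated, roster$pim)
    ),
    ssr_stats = list(
      total = nrow(ssrTruth),
      cultivated_polymorphic = polyIn(ssrCounts, cultivated),
      wild_polymorphic = polyIn(ssrCounts, wildSubset),
      shared_with_pim = sharedIn(ssrCounts, cultivated, roster$pim)
    ),
    ssr_truth = ssrTruth,
    ssr_counts = ssrCounts,
    tr_truth = ref$tr,
    indel_truth = indelTruth,
    pairwise_truth = setNames(as.integer(rowSums(carrierM)), ids),
    subsets = list(cultivated = cultivated, wild = wildSubset,
                   pimpinellifolium = roster$pim, local = roster$loc,
                   cer1 = roster$cer[1L]),
    structure = ref$structure,
    genes = ref$genes
  )

  new("SimulatedPanel",
    alignment = aln, sequences = seqs, annotation = ref$annotation,
    structure = ref$structure, scheme = scheme,
    tree = .simTrueTree(roster, config$other_counts[["pim_pair"]] > 0L),
    truth = truth, config = config)
}
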