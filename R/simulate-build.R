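# Place elements (genes, SSR arrays, TR arrays) left to right in a region
# with randomized order and randomized inter-element gaps (>= minGap).
.simLayoutRegion <- function(lens, regionStart, regionLen, minGap = 30L) {
  n <- length(lens)
  extra <- regionLen - sum(lens) - minGap * (n + 1L)
  .check(extra >= 0L,
         "infeasible packing: %d bp of elements + gaps exceed the %d bp region",
         sum(lens) + minGap * (n + 1L), regionLen)
  ord <- sample.int(n)
  gapExtra <- if (extra > 0L) stats::rmultinom(1L, extra, rep.int(1, n + 1L))[, 1L]
    else rep(0L, n + 1L)
  starts <- integer(n)
  cursor <- regionStart
  for (k in seq_len(n)) {
    cursor <- cursor + minGap + gapExtra[k]
    starts[ord[k]] <- cursor
    cursor <- cursor + lens[ord[k]]
  }
  starts
}

# Pick a replacement base different from `avoid`, preferring also to differ
# from `soft` constraints (neighbour bases) to avoid creating repeat runs.
.simPickBase <- function(avoid, soft = character(0)) {
  bases <- c("A", "C", "G", "T")
  cand <- setdiff(bases, c(avoid, soft))
  if (length(cand) == 0L) cand <- setdiff(bases, avoid)
  cand[1L]
}

# Break periodic extension of a planted array at its flanks.
.simFixFlanks <- function(v, start, end, period) {
  n <- length(v)
  b <- .wrap1(start - 1L, n)
  if (v[b] == v[.wrap1(b + period, n)])
    v[b] <- .simPickBase(c(v[.wrap1(b + period, n)], v[.wrap1(b - 1L, n)], v[.wrap1(b + 1L, n)]))
  a <- .wrap1(end + 1L, n)
  if (v[a] == v[.wrap1(a - period, n)])
    v[a] <- .simPickBase(c(v[.wrap1(a - period, n)], v[.wrap1(a - 1L, n)], v[.wrap1(a + 1L, n)]))
  v
}

# Repeat-hygiene loop: make the detector output on the reference equal the
# plan exactly (no accidental repeats, no chance extensions). Any fix that
# lands inside an inverted-repeat copy is mirrored by rebuilding IRb as the
# exact reverse complement of IRa; the four region junctions are re-guarded
# against chance extension of the IR pair after every pass.
.simRepeatHygiene <- function(v, ssrExp, trExp, ira, irb, maxIter = 60L) {
  n <- length(v)
  nL <- ira[1L] - 1L
  sscStart <- ira[2L] + 1L
  sscEnd <- irb[1L] - 1L
  enforceStructure <- function(v) {
    v[irb[1L]:irb[2L]] <- rev(.compVec(v[ira[1L]:ira[2L]]))
    if (v[nL] == .COMPLEMENT[[v[1L]]])
      v[1L] <- .simPickBase(c(.COMPLEMENT[[v[nL]]], v[2L], v[n]))
    if (v[sscStart] == .COMPLEMENT[[v[sscEnd]]])
      v[sscStart] <- .simPickBase(c(.COMPLEMENT[[v[sscEnd]]],
                                    v[sscStart + 1L], v[sscStart - 1L]))
    v
  }
  v <- enforceStructure(v)
  for (iter in seq_len(maxIter)) {
    clean <- TRUE
    s <- .fromVec(v)
    found <- findSSRs(s, circular = TRUE)
    for (i in seq_len(nrow(found))) {
      hit <- which(ssrExp$start == found$start[i] & ssrExp$end == found$end[i] &
                   ssrExp$unit == found$unit[i])
      if (length(hit) == 1L) next
      clean <- FALSE
      near <- which(pmax(ssrExp$start, found$start[i]) <=
                    pmin(ssrExp$end, found$end[i]))
      if (length(near) >= 1L) {
        v <- .simFixFlanks(v, ssrExp$start[near[1L]], ssrExp$end[near[1L]],
                           ssrExp$unit[near[1L]])
      } else {
        mid <- .wrap1(found$start[i] + found$length[i] %/% 2L, length(v))
        v[mid] <- .simPickBase(c(v[mid], v[.wrap1(mid - 1L, length(v))],
                                 v[.wrap1(mid + 1L, length(v))],
                                 v[.wrap1(mid - 2L, length(v))],
                                 v[.wrap1(mid + 2L, length(v))]))
      }
    }
    s <- .fromVec(v)
    foundTr <- findTandemRepeats(s, circular = TRUE)
    for (i in seq_len(nrow(foundTr))) {
      hit <- which(trExp$start == foundTr$start[i] & trExp$end == foundTr$end[i] &
                   trExp$period == foundTr$period[i])
      if (length(hit) == 1L) next
      clean <- FALSE
      near <- which(pmax(trExp$start, foundTr$start[i]) <=
                    pmin(trExp$end, foundTr$end[i]))
      if (length(near) >= 1L) {
        v <- .simFixFlanks(v, trExp$start[near[1L]], trExp$end[near[1L]],
                           trExp$period[near[1L]])
      } else {
        mid <- .wrap1(foundTr$start[i] + foundTr$total_length[i] %/% 2L, length(v))
        v[mid] <- .simPickBase(c(v[mid], v[.wrap1(mid - 1L, length(v))],
                                 v[.wrap1(mid + 1L, length(v))]))
      }
    }
    v2 <- enforceStructure(v)
    if (!identical(v2, v)) clean <- FALSE
    v <- v2
    if (clean) {
      # everything found matches the plan; also require nothing missing
      okS <- nrow(found) == nrow(ssrExp)
      okT <- nrow(foundTr) == nrow(trExp)
      if (okS && okT) return(v)
      clean <- FALSE
      missS <- which(!(paste(ssrExp$start, ssrExp$unit) %in%
                       paste(found$start, found$unit)))
      for (i in missS) {
        len <- ssrExp$end[i] - ssrExp$start[i] + 1L
        v[seq.int(ssrExp$start[i], ssrExp$end[i])] <-
          .toVec(strrep(ssrExp$motif[i], len %/% ssrExp$unit[i]))
        v <- .simFixFlanks(v, ssrExp$start[i], ssrExp$end[i], ssrExp$unit[i])
      }
    }
  }
  stop("repeat hygiene did not converge; sequence keeps spawning accidental repeats",
       call. = FALSE)
}

#' Generate a synthetic reference plastome with planted features
#'
#' Builds a random quadripartite genome (IRb the exact reverse complement of
#' IRa), places the gene roster, SSR arrays and perfect tandem repeats
#' non-overlapping in the single-copy regions, and scrubs the background so
#' that repeat detectors report exactly the planted loci.
#'
#' @param config a [simulationConfig()].
#' @return list with `sequence` (character string), `annotation`
#'   ([PlastomeAnnotation-class]), `structure` ([QuadripartiteStructure-class]
#'   truth), `genes` (placed gene table), `ssr` (placed SSR plan) and `tr`
#'   (placed tandem-repeat plan).
#' @export
generateReference <- function(config) {
  set.seed(config$seed)
  nL <- config$lsc_length; nI <- config$ir_length; nS <- config$ssc_length
  n <- config$genome_length

  genes <- .simGeneRoster(config)
  ssrPlan <- .simSsrPlan(config)
  trPlan <- .simTrPlan(config)

  # region assignment for repeat loci (SSRs ~75% LSC, TRs ~70% LSC)
  ssrPlan$region <- "LSC"
  nSsrSsc <- round(0.25 * nrow(ssrPlan))
  if (nSsrSsc > 0L) ssrPlan$region[sample.int(nrow(ssrPlan), nSsrSsc)] <- "SSC"
  trPlan$region <- "LSC"
  nTrSsc <- round(0.3 * nrow(trPlan))
  if (nTrSsc > 0L) trPlan$region[sample.int(nrow(trPlan), nTrSsc)] <- "SSC"

  layoutOne <- function(region, regionStart, regionLen) {
    gi <- which(genes$region == region)
    si <- which(ssrPlan$region == region)
    ti <- which(trPlan$region == region)
    lens <- c(genes$span[gi], ssrPlan$array_len[si], trPlan$array_len[ti])
    starts <- .simLayoutRegion(lens, regionStart, regionLen)
    list(gene = setNames(starts[seq_along(gi)], gi),
         ssr = setNames(starts[length(gi) + seq_along(si)], si),
         tr = setNames(starts[length(gi) + length(si) + seq_along(ti)], ti))
  }
  genes$start <- NA_integer_
  ssrPlan$start <- NA_integer_
  trPlan$start <- NA_integer_
  layL <- layoutOne("LSC", 1L, nL)
  layS <- layoutOne("SSC", nL + nI + 1L, nS)

  for (lay in list(layL, layS)) {
    genes$start[as.integer(names(lay$gene))] <- unname(lay$gene)
    ssrPlan$start[as.integer(names(lay$ssr))] <- unname(lay$ssr)
    trPlan$start[as.integer(names(lay$tr))] <- unname(lay$tr)
  }
  genes$end <- genes$start + genes$span - 1L
  ssrPlan$end <- ssrPlan$start + ssrPlan$array_len - 1L
  trPlan$end <- trPlan$start + trPlan$array_len - 1L

  # background sequence; IRb mirrors IRa
  ira <- .simRandomBases(nI, config$gc)
  v <- c(.simRandomBases(nL, config$gc), ira, .simRandomBases(nS, config$gc),
         rev(.compVec(ira)))

  # stamp repeat arrays, then break chance extensions at their flanks
  for (i in seq_len(nrow(ssrPlan))) {
    arr <- .toVec(strrep(ssrPlan$motif[i], ssrPlan$ref_units[i]))
    v[seq.int(ssrPlan$start[i], ssrPlan$end[i])] <- arr
  }
  for (i in seq_len(nrow(trPlan))) {
    arr <- .toVec(strrep(trPlan$unit[i], 2L))
    v[seq.int(trPlan$start[i], trPlan$end[i])] <- arr
  }
  for (i in seq_len(nrow(ssrPlan)))
    v <- .simFixFlanks(v, ssrPlan$start[i], ssrPlan$end[i], ssrPlan$unit[i])
  for (i in seq_len(nrow(trPlan)))
    v <- .simFixFlanks(v, trPlan$start[i], trPlan$end[i], trPlan$period[i])

  sscStart <- nL + nI + 1L; sscEnd <- nL + nI + nS
  ssrExp <- data.frame(start = ssrPlan$start, end = ssrPlan$end,
                       unit = ssrPlan$unit, motif = ssrPlan$motif,
                       stringsAsFactors = FALSE)
  trExp <- data.frame(start = trPlan$start, end = trPlan$end, period = trPlan$period)
  v <- .simRepeatHygiene(v, ssrExp, trExp,
                         ira = c(nL + 1L, nL + nI), irb = c(sscEnd + 1L, n))

  # annotation table: CDS/tRNA/rRNA intervals (gene spans derived)
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    gkind <- genes$kind[i]
    exons <- genes$exon_lens[[i]]
    if (length(exons) == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = paste0(tolower(gkind), ":", genes$gene[i]),
        gene = genes$gene[i], kind = gkind,
        start = genes$start[i], end = genes$end[i],
        strand = genes$strand[i], phase = 0L, exon_rank = 1L,
        stringsAsFactors = FALSE)
    } else {
      # genomic order; translation rank 1 is the rightmost exon on '-'
      glens <- if (genes$strand[i] == "+") exons else rev(exons)
      e1 <- c(genes$start[i], genes$start[i] + glens[1L] - 1L)
      e2 <- c(genes$end[i] - glens[2L] + 1L, genes$end[i])
      ranks <- if (genes$strand[i] == "+") c(1L, 2L) else c(2L, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = paste0("cds:", genes$gene[i]), gene = genes$gene[i],
        kind = "CDS", start = c(e1[1L], e2[1L]), end = c(e1[2L], e2[2L]),
        strand = genes$strand[i], phase = 0L, exon_rank = ranks,
        stringsAsFactors = FALSE)
    }
  }
  ann <- .makeAnnotation(do.call(rbind, rows), n)

  structure <- new("QuadripartiteStructure",
    lsc = c(1L, nL), ira = c(nL + 1L, nL + nI),
    ssc = c(sscStart, sscEnd), irb = c(sscEnd + 1L, n),
    genomeLength = n, canonicalOrder = TRUE)

  list(sequence = .fromVec(v), annotation = ann, structure = structure,
       genes = genes, ssr = ssrPlan, tr = trPlan)
}
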