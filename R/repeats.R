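#' Default MISA-style SSR detection thresholds
#'
#' Minimum repeat-unit counts per unit size: 1/8, 2/6, 3/5, 4/5, 5/5, 6/5.
#' @export
ssrThresholds <- function() c(`1` = 8L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)

# Maximal perfect periodic runs at a fixed period on a base vector.
# Returns data.frame(start, total_len) where the periodic stretch is
# start..start+total_len-1 (start in circular coordinates when circular).
.periodicRuns <- function(v, period, circular) {
  n <- length(v)
  if (n <= period) return(data.frame(start = integer(), total_len = integer()))
  if (circular) {
    m <- v == v[.wrap1(seq_len(n) + period, n)]
    r <- rle(m)
    if (all(m)) return(data.frame(start = 1L, total_len = n))
    starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
    idx <- which(r$values)
    out <- data.frame(start = starts[idx], total_len = r$lengths[idx] + period)
    # merge a run wrapping through the origin
    k <- length(r$values)
    if (r$values[1L] && r$values[k]) {
      first <- which(out$start == starts[1L])
      last <- which(out$start == starts[k])
      out$start[last] <- starts[k]
      out$total_len[last] <- r$lengths[k] + r$lengths[1L] + period
      out <- out[-first, , drop = FALSE]
    }
    out$total_len <- pmin(out$total_len, n)
    out
  } else {
    m <- v[seq_len(n - period)] == v[seq_len(n - period) + period]
    r <- rle(m)
    starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
    idx <- which(r$values)
    data.frame(start = starts[idx], total_len = r$lengths[idx] + period)
  }
}

# Extract total_len characters circularly from position start.
.circSubstr <- function(v, start, len) {
  n <- length(v)
  .fromVec(v[.wrap1(seq.int(start, length.out = len), n)])
}

#' Find simple sequence repeats (microsatellites) in one genome
#'
#' Reports maximal perfect runs of a primitive 1-6 bp motif whose repeat-unit
#' count meets the unit-size threshold. A run qualifying at several unit sizes
#' (a poly-A run seen as mono- or di-nucleotide) is reported only for its
#' primitive motif; overlapping reports across unit sizes are resolved in
#' favour of the smaller unit.
#'
#' @param genome character string / DNAString / single DNAStringSet entry
#'   (uppercase `{A,C,G,T,N}`).
#' @param thresholds named integer vector, unit size -> minimum units
#'   (default [ssrThresholds()]).
#' @param circular treat the sequence as circular (runs may wrap the origin).
#' @return data.frame with columns `start`, `end` (1-based inclusive; `end`
#'   may wrap past the origin when circular), `motif` (as occurring),
#'   `canonical` (canonical motif), `unit`, `units` (complete units),
#'   `length` (bp of the maximal periodic stretch).
#' @examples
#' findSSRs(paste0("GCGC", strrep("A", 9), "GCGCGCGCGCGC"), circular = FALSE)
#' @export
findSSRs <- function(genome, thresholds = ssrThresholds(), circular = TRUE) {
  s <- .asSequenceString(genome)
  v <- .toVec(s)
  n <- length(v)
  out <- list()
  for (u in as.integer(names(thresholds))) {
    runs <- .periodicRuns(v, u, circular)
    if (nrow(runs) == 0L) next
    units <- runs$total_len %/% u
    keep <- units >= thresholds[[as.character(u)]]
    runs <- runs[keep, , drop = FALSE]
    units <- units[keep]
    if (nrow(runs) == 0L) next
    motifs <- vapply(runs$start, function(p) .circSubstr(v, p, u), character(1))
    prim <- vapply(motifs, .isPrimitive, logical(1))
    valid <- prim & !grepl("N", motifs, fixed = TRUE)
    runs <- runs[valid, , drop = FALSE]
    if (nrow(runs) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      start = runs$start,
      end = runs$start + runs$total_len - 1L,   # may exceed n when wrapping
      motif = motifs[valid],
      canonical = vapply(motifs[valid], canonicalMotif, character(1)),
      unit = u,
      units = units[valid],
      length = runs$total_len,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      canonical = character(), unit = integer(),
                      units = integer(), length = integer()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$unit, df$start), , drop = FALSE]
  # no overlapping reports: smaller unit sizes win
  keep <- rep(TRUE, nrow(df))
  covered <- integer(0)
  for (i in seq_len(nrow(df))) {
    pos <- .wrap1(seq.int(df$start[i], length.out = df$length[i]), n)
    if (any(pos %in% covered)) {
      keep[i] <- FALSE
    } else {
      covered <- c(covered, pos)
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Canonical form of an SSR motif
#'
#' The lexicographically smallest rotation of the motif's primitive root.
#' Strands are not collapsed: `TA` canonicalizes to `AT`, but a motif and its
#' reverse complement stay distinct.
#'
#' @param motif character string of length 1-6 (longer motifs are accepted and
#'   reduced to their primitive root first).
#' @return the canonical motif string.
#' @examples
#' canonicalMotif("TA")   # "AT"
#' canonicalMotif("AGA")  # "AAG"
#' @export
canonicalMotif <- function(motif) {
  .check(nchar(motif) >= 1L, "empty motif")
  p <- .primitivePeriod(motif)
  root <- substr(motif, 1L, p)
  v <- .toVec(root)
  rots <- vapply(seq_len(p), function(r) {
    .fromVec(v[.wrap1(seq_len(p) + r - 1L, p)])
  }, character(1))
  min(rots)
}

#' Find perfect tandem repeats in one genome
#'
#' Maximal perfect tandem arrays with period between `minPeriod` and
#' `maxPeriod`, at least `minCopies` copies and total length at least
#' `minTotalLen`. Arrays whose unit is itself periodic are reported once at
#' the smallest period; `minPeriod = 7` keeps the search disjoint from SSR
#' space (unit size <= 6).
#'
#' @inheritParams findSSRs
#' @param minPeriod,maxPeriod period bounds in bp.
#' @param minCopies minimum (possibly fractional) copy number.
#' @param minTotalLen minimum array length in bp.
#' @return data.frame with columns `start`, `end`, `period`, `copy_number`,
#'   `total_length`, `unit` (the repeat unit string).
#' @examples
#' unit <- "ACGTTGCAGGCTA"  # 13 bp
#' findTandemRepeats(paste0("GG", strrep(unit, 2), "TT"), circular = FALSE)
#' @export
findTandemRepeats <- function(genome, minPeriod = 7L, maxPeriod = 100L,
                              minCopies = 2.0, minTotalLen = 26L,
                              circular = TRUE) {
  s <- .asSequenceString(genome)
  v <- .toVec(s)
  n <- length(v)
  out <- list()
  for (p in seq.int(minPeriod, min(maxPeriod, max(minPeriod, n - 1L)))) {
    runs <- .periodicRuns(v, p, circular)
    if (nrow(runs) == 0L) next
    keep <- runs$total_len >= max(minTotalLen, ceiling(minCopies * p))
    runs <- runs[keep, , drop = FALSE]
    if (nrow(runs) == 0L) next
    units <- vapply(runs$start, function(st) .circSubstr(v, st, p), character(1))
    prim <- vapply(units, .primitivePeriod, integer(1)) == p &
      !grepl("N", units, fixed = TRUE)
    runs <- runs[prim, , drop = FALSE]
    if (nrow(runs) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      start = runs$start,
      end = runs$start + runs$total_len - 1L,
      period = p,
      copy_number = runs$total_len / p,
      total_length = runs$total_len,
      unit = units[prim],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), total_length = integer(),
                      unit = character()))
  }
  df <- do.call(rbind, out)
  df <- df[df$copy_number >= minCopies, , drop = FALSE]
  df <- df[order(df$start, df$period), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Cross-genotype SSR locus table
#'
#' Projects per-genome SSR detections onto reference coordinates through the
#' alignment, merges loci whose projected intervals overlap with matching
#' canonical motifs, and recounts the repeat-unit number of every genotype
#' (including those below the detection threshold) from its own ungapped
#' sequence at the locus.
#'
#' @param msa a [PlastomeAlignment-class].
#' @param perGenomeSsrs optional named list of per-genome [findSSRs()] tables
#'   computed on the ungapped sequences; computed internally when `NULL`.
#' @param thresholds detection thresholds, as in [findSSRs()].
#' @param ann optional [PlastomeAnnotation-class] for context labels.
#' @param structure optional [QuadripartiteStructure-class] for region labels.
#' @return an [SsrTable-class].
#' @export
buildSsrLocusTable <- function(msa, perGenomeSsrs = NULL,
                               thresholds = ssrThresholds(),
                               ann = NULL, structure = NULL) {
  stopifnot(is(msa, "PlastomeAlignment"))
  M <- alignmentMatrix(msa)
  ids <- rownames(M)
  refRow <- M[msa@referenceId, ]
  refPosOfCol <- cumsum(refRow != "-")
  rowSeqs <- lapply(ids, function(g) M[g, ][M[g, ] != "-"])
  names(rowSeqs) <- ids
  colOfPos <- lapply(ids, function(g) which(M[g, ] != "-"))
  names(colOfPos) <- ids

  if (is.null(perGenomeSsrs)) {
    perGenomeSsrs <- lapply(rowSeqs, function(v) {
      findSSRs(.fromVec(v), thresholds = thresholds, circular = FALSE)
    })
  }

  proj <- list()
  for (g in ids) {
    t0 <- perGenomeSsrs[[g]]
    if (is.null(t0) || nrow(t0) == 0L) next
    cm <- colOfPos[[g]]
    cs <- cm[t0$start]
    ce <- cm[pmin(t0$end, length(cm))]
    proj[[g]] <- data.frame(
      genotype = g,
      ref_start = refPosOfCol[cs], ref_end = refPosOfCol[ce],
      canonical = t0$canonical, unit = t0$unit,
      stringsAsFactors = FALSE
    )
  }
  proj <- do.call(rbind, proj)
  .check(!is.null(proj) && nrow(proj) > 0L, "no SSRs detected in any genotype")
  proj$ref_start <- pmax(proj$ref_start, 1L)

  # merge overlapping projections with identical canonical motif
  loci <- list()
  for (cm in unique(proj$canonical)) {
    sub <- proj[proj$canonical == cm, , drop = FALSE]
    sub <- sub[order(sub$ref_start), , drop = FALSE]
    curS <- sub$ref_start[1L]; curE <- sub$ref_end[1L]; u <- sub$unit[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$ref_start[i] <= curE) {
        curE <- max(curE, sub$ref_end[i])
      } else {
        loci[[length(loci) + 1L]] <- data.frame(
          ref_start = curS, ref_end = curE, motif = cm, unit = u,
          stringsAsFactors = FALSE)
        curS <- sub$ref_start[i]; curE <- sub$ref_end[i]
      }
    }
    loci[[length(loci) + 1L]] <- data.frame(
      ref_start = curS, ref_end = curE, motif = cm, unit = u,
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, loci)
  loci <- loci[order(loci$ref_start, loci$motif), , drop = FALSE]
  rownames(loci) <- NULL

  # loci of different motifs overlapping on the reference: kept separate
  if (nrow(loci) > 1L) {
    o <- order(loci$ref_start)
    s <- loci$ref_start[o]; e <- loci$ref_end[o]
    if (any(s[-1L] <= e[-length(e)] &
            loci$motif[o][-1L] != loci$motif[o][-length(o)]))
      warning("overlapping SSR projections with different motifs kept as separate loci")
  }

  counts <- matrix(NA_integer_, nrow = length(ids), ncol = nrow(loci),
                   dimnames = list(ids, NULL))
  meets <- matrix(FALSE, nrow = length(ids), ncol = nrow(loci),
                  dimnames = list(ids, NULL))
  for (li in seq_len(nrow(loci))) {
    colSpan <- which(refPosOfCol >= loci$ref_start[li] &
                     refPosOfCol <= loci$ref_end[li])
    u <- loci$unit[li]
    thr <- thresholds[[as.character(u)]]
    for (g in ids) {
      chars <- M[g, colSpan]
      chars <- chars[chars != "-"]
      if (length(chars) == 0L) next
      cnt <- .maxPeriodicUnits(chars, u, loci$motif[li])
      counts[g, li] <- cnt
      meets[g, li] <- !is.na(cnt) && cnt >= thr
    }
  }
  nd <- apply(counts, 2L, function(x) length(unique(x[!is.na(x)])))
  loci$polymorphic <- nd >= 2L
  if (!is.null(ann)) loci$context <- contextOf(loci$ref_start, ann)
  if (!is.null(structure)) loci$region <- regionOf(loci$ref_start, structure)
  new("SsrTable", loci = loci, counts = counts, meets = meets)
}

# Longest perfect periodic stretch (period u, canonical motif cm) within a
# gapless character vector; returns complete units.
.maxPeriodicUnits <- function(chars, u, cm) {
  n <- length(chars)
  if (n < u) return(0L)
  m <- if (n > u) chars[seq_len(n - u)] == chars[seq_len(n - u) + u] else logical(0)
  best <- 0L
  if (length(m)) {
    r <- rle(m)
    starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
    for (i in which(r$values)) {
      tot <- r$lengths[i] + u
      mot <- .fromVec(chars[seq.int(starts[i], length.out = u)])
      if (canonicalMotif(mot) == cm) best <- max(best, tot %/% u)
    }
  }
  if (best == 0L) {
    # no run of >= 2 units; check for a single exact unit occurrence
    for (st in seq_len(n - u + 1L)) {
      mot <- .fromVec(chars[seq.int(st, length.out = u)])
      if (nchar(mot) == u && canonicalMotif(mot) == cm) return(1L)
    }
    return(0L)
  }
  best
}
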