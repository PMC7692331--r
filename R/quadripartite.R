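# Numeric 4^k encoding of every k-mer of a base vector (A,C,G,T -> 0..3).
# Values are exact doubles for k <= 26 (4^26 < 2^53).
.kmerCodes <- function(baseVec, k) {
  code <- c(A = 0, C = 1, G = 2, T = 3)[baseVec]
  n <- length(code)
  if (n < k) return(numeric(0))
  out <- numeric(n - k + 1L)
  for (t in 0:(k - 1L)) {
    out <- out * 4 + code[(1L + t):(n - k + 1L + t)]
  }
  out
}

# All maximal exact inverted-repeat pairs of a circular sequence with length
# >= minLen, via k-mer seeds grouped by diagonal on the doubled sequence.
# Returns a data.frame (i, j, len) in 1-based circular coordinates, i < j or
# i == min circular start of the pair.
.maximalInvertedRepeats <- function(s, minLen, k = 25L) {
  n <- nchar(s)
  k <- min(k, minLen)
  v <- .toVec(s)
  v2 <- c(v, v)
  rc2 <- rev(.compVec(v2))
  vS <- .kmerCodes(v2, k)
  vR <- .kmerCodes(rc2, k)
  shared <- intersect(vS, vR)
  if (length(shared) == 0L) return(data.frame(i = integer(), j = integer(), len = integer()))
  fS <- match(vS, shared)
  fR <- match(vR, shared)
  sS <- split(seq_along(vS), fS)
  sR <- split(seq_along(vR), fR)
  sR <- sR[names(sS)]
  # drop hyper-repetitive seeds that cannot belong to a unique IR pair
  ok <- lengths(sS) <= 40L & lengths(sR) <= 40L
  sS <- sS[ok]; sR <- sR[ok]
  if (length(sS) == 0L) return(data.frame(i = integer(), j = integer(), len = integer()))
  a <- unlist(mapply(function(x, y) rep(x, each = length(y)), sS, sR,
                     SIMPLIFY = FALSE), use.names = FALSE)
  b <- unlist(mapply(function(x, y) rep(y, times = length(x)), sS, sR,
                     SIMPLIFY = FALSE), use.names = FALSE)
  d <- a - b
  o <- order(d, a)
  aa <- a[o]; dd <- d[o]; bb <- b[o]
  newRun <- c(TRUE, dd[-1L] != dd[-length(dd)] | aa[-1L] != aa[-length(aa)] + 1L)
  runId <- cumsum(newRun)
  a0 <- aa[newRun]          # first seed of each run (a ascending within run)
  b0 <- bb[newRun]
  runLen <- tabulate(runId)
  L <- runLen + k - 1L
  # map the rc2 window back to doubled-sequence coordinates
  j2start <- 2L * n - (b0 + L - 1L) + 1L
  ci <- .wrap1(as.integer(a0), n)
  cj <- .wrap1(as.integer(j2start), n)
  L <- pmin(L, n)
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  df <- data.frame(i = lo, j = hi, len = as.integer(L))
  df <- df[df$len >= minLen & df$i != df$j, , drop = FALSE]
  if (nrow(df) == 0L) return(df)
  # keep the maximal version of each circular pair
  key <- paste(df$i, df$j, sep = ":")
  df <- df[order(key, -df$len), , drop = FALSE]
  df <- df[!duplicated(paste(df$i, df$j, sep = ":")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# TRUE when two circular intervals of length len starting at i and j overlap.
.circOverlap <- function(i, j, len, n) {
  pi <- .wrap1(seq.int(i, length.out = len), n)
  pj <- .wrap1(seq.int(j, length.out = len), n)
  any(pi %in% pj)
}

#' Detect the quadripartite LSC/SSC/IRa/IRb structure of a plastome
#'
#' Finds the longest pair of non-overlapping, exact, maximal inverted repeats
#' of length at least `minIrLen` on the circular sequence (seed-and-extend
#' with a 25-mer index against the reverse complement), then labels the two
#' single-copy gaps as LSC (larger) and SSC (smaller). `IRa` is the repeat
#' copy that immediately follows the LSC in circular order.
#'
#' @param genome a character string, [Biostrings::DNAString] or single-entry
#'   DNAStringSet.
#' @param minIrLen minimum inverted-repeat length (bp).
#' @return a [QuadripartiteStructure-class].
#' @examples
#' set.seed(1)
#' L <- paste(sample(c("A","C","G","T"), 5000, TRUE), collapse = "")
#' I <- paste(sample(c("A","C","G","T"), 1200, TRUE), collapse = "")
#' S <- paste(sample(c("A","C","G","T"), 800, TRUE), collapse = "")
#' q <- detectQuadripartite(paste0(L, I, S, plastomeVar:::.revcomp(I)),
#'                          minIrLen = 500)
#' regionLengths(q)
#' @export
detectQuadripartite <- function(genome, minIrLen = 1000L) {
  s <- .asSequenceString(genome)
  n <- nchar(s)
  .check(n >= 4L * minIrLen,
         "genome length %d below 4 x min_ir_len (%d); degenerate input", n, minIrLen)
  reps <- .maximalInvertedRepeats(s, minLen = minIrLen)
  if (nrow(reps) == 0L)
    stop("no quadripartite structure: no inverted repeat >= ", minIrLen, " bp",
         call. = FALSE)
  reps <- reps[order(-reps$len, reps$i, reps$j), , drop = FALSE]
  best <- reps[1L, ]
  if (.circOverlap(best$i, best$j, best$len, n))
    stop("no quadripartite structure: best inverted repeat pair overlaps ",
         "(palindromic degenerate case)", call. = FALSE)
  irLen <- best$len
  e1 <- .wrap1(best$i + irLen - 1L, n)
  e2 <- .wrap1(best$j + irLen - 1L, n)
  gap1 <- c(.wrap1(e1 + 1L, n), .wrap1(best$j - 1L, n))  # after copy1, before copy2
  gap2 <- c(.wrap1(e2 + 1L, n), .wrap1(best$i - 1L, n))  # after copy2, before copy1
  len1 <- .circLen(gap1[1L], gap1[2L], n)
  len2 <- .circLen(gap2[1L], gap2[2L], n)
  .check(len1 + len2 + 2L * irLen == n, "internal error: region lengths do not sum")
  .check(len1 != len2, "single-copy regions of equal size; LSC/SSC labels undefined")
  if (len1 > len2) {
    lsc <- gap1; ssc <- gap2
    ira <- c(best$j, e2); irb <- c(best$i, e1)  # IRa follows LSC
  } else {
    lsc <- gap2; ssc <- gap1
    ira <- c(best$i, e1); irb <- c(best$j, e2)
  }
  canonical <- lsc[1L] == 1L && lsc[2L] < ira[1L] && ira[2L] < ssc[1L] &&
    ssc[2L] < irb[1L] && irb[2L] == n
  new("QuadripartiteStructure",
    lsc = as.integer(lsc), ssc = as.integer(ssc),
    ira = as.integer(ira), irb = as.integer(irb),
    genomeLength = as.integer(n), canonicalOrder = isTRUE(canonical)
  )
}

# Accept character / DNAString / single DNAStringSet entry.
.asSequenceString <- function(genome) {
  if (is.character(genome)) {
    .check(length(genome) == 1L, "expected a single sequence")
    return(toupper(genome))
  }
  if (is(genome, "DNAStringSet")) {
    .check(length(genome) == 1L, "expected a single sequence")
    return(as.character(genome[[1L]]))
  }
  as.character(genome)
}

#' Region label of reference positions
#'
#' @param positions integer vector of 1-based positions.
#' @param q a [QuadripartiteStructure-class].
#' @return character vector over `{"LSC","SSC","IRa","IRb"}`.
#' @export
regionOf <- function(positions, q) {
  stopifnot(is(q, "QuadripartiteStructure"))
  n <- q@genomeLength
  .check(all(positions >= 1L & positions <= n), "position out of range [1, %d]", n)
  inReg <- function(p, iv) {
    if (iv[2L] >= iv[1L]) p >= iv[1L] & p <= iv[2L] else p >= iv[1L] | p <= iv[2L]
  }
  out <- rep(NA_character_, length(positions))
  out[inReg(positions, q@lsc)] <- "LSC"
  out[inReg(positions, q@ssc)] <- "SSC"
  out[inReg(positions, q@ira)] <- "IRa"
  out[inReg(positions, q@irb)] <- "IRb"
  .check(!anyNA(out), "internal error: unlabeled position")
  out
}

#' Structure summary table across genotypes
#'
#' One row per genotype with total, LSC, SSC and IR lengths (the single
#' reported IR length is that of IRb, identical to IRa by construction).
#'
#' @param structures named list of [QuadripartiteStructure-class] objects.
#' @return data.frame with columns `genotype`, `total`, `lsc`, `ssc`, `ir`.
#' @export
structureTable <- function(structures) {
  rows <- lapply(names(structures), function(id) {
    l <- regionLengths(structures[[id]])
    data.frame(genotype = id, total = l[["total"]], lsc = l[["lsc"]],
               ssc = l[["ssc"]], ir = l[["irb"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' BED export of the four plastome regions
#'
#' @param q a [QuadripartiteStructure-class].
#' @param seqid sequence name for the BED chrom column.
#' @return data.frame in BED3+name layout (0-based half-open intervals);
#'   regions wrapping the origin are split into two BED lines.
#' @export
regionsToBed <- function(q, seqid = "plastome") {
  n <- q@genomeLength
  one <- function(iv, nm) {
    if (iv[2L] >= iv[1L]) {
      data.frame(chrom = seqid, start = iv[1L] - 1L, end = iv[2L], name = nm)
    } else {
      rbind(
        data.frame(chrom = seqid, start = iv[1L] - 1L, end = n, name = nm),
        data.frame(chrom = seqid, start = 0L, end = iv[2L], name = nm)
      )
    }
  }
  rbind(one(q@lsc, "LSC"), one(q@ira, "IRa"), one(q@ssc, "SSC"), one(q@irb, "IRb"))
}
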