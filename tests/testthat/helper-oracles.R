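# Independent brute-force oracles and toy builders used across the suite.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

randSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcompStr <- function(s) {
  paste(rev(unname(COMP[strsplit(s, "")[[1]]])), collapse = "")
}

# Toy circular genome L + I + S + revcomp(I) with junction bases guarded so
# the planted inverted repeat cannot extend by chance.
plantedIrToy <- function(nL, nI, nS, seed) {
  set.seed(seed)
  repeat {
    L <- strsplit(randSeq(nL), "")[[1]]
    I <- strsplit(randSeq(nI), "")[[1]]
    S <- strsplit(randSeq(nS), "")[[1]]
    ok1 <- L[nL] != COMP[[L[1]]]       # LSC-side junction
    ok2 <- S[1] != COMP[[S[nS]]]       # SSC-side junction
    if (ok1 && ok2) break
  }
  paste(c(L, I, S, rev(unname(COMP[I]))), collapse = "")
}

# O(n^2) enumeration of all maximal inverted-repeat pairs (linear sequence).
invertedRepeatOracle <- function(s, minLen) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  rcv <- rev(unname(COMP[v]))
  out <- list()
  for (d in seq.int(-(n - 1L), n - 1L)) {
    i <- seq.int(max(1L, 1L + d), min(n, n + d))
    q <- i - d
    m <- v[i] == rcv[q]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= minLen)) {
      a <- i[starts[k]]; len <- r$lengths[k]
      qa <- a - d
      j <- n - (qa + len - 1L) + 1L      # s-coordinate of the partner copy
      lo <- min(a, j); hi <- max(a, j)
      out[[length(out) + 1L]] <- c(lo, hi, len)
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(), len = integer()))
  df <- unique(do.call(rbind, out))
  df <- data.frame(i = df[, 1], j = df[, 2], len = df[, 3])
  df[order(df$i, df$j), ]
}

# Brute-force SSR scan: every start x unit size, maximal perfect runs,
# primitive motifs, thresholds, then the smaller-unit-wins overlap rule.
ssrOracle <- function(s, thresholds = c(`1` = 8, `2` = 6, `3` = 5, `4` = 5, `5` = 5, `6` = 5)) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  isPrim <- function(m) {
    k <- length(m)
    for (p in seq_len(k - 1)) {
      if (k %% p == 0 && all(m == rep(m[seq_len(p)], k / p))) return(FALSE)
    }
    TRUE
  }
  cand <- list()
  for (u in as.integer(names(thresholds))) {
    i <- 1L
    while (i + u - 1L <= n) {
      # maximal run check: previous position must break periodicity
      if (i > 1L && i + u - 1L <= n && v[i - 1L] == v[i - 1L + u]) { i <- i + 1L; next }
      j <- i
      while (j + u <= n && v[j] == v[j + u]) j <- j + 1L
      total <- (j - i) + u
      units <- total %/% u
      if (units >= thresholds[[as.character(u)]] && isPrim(v[i:(i + u - 1L)])) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = i, end = i + total - 1L, unit = u, units = units)
      }
      i <- i + 1L
    }
  }
  if (!length(cand)) return(data.frame(start = integer(), end = integer(),
                                       unit = integer(), units = integer()))
  df <- unique(do.call(rbind, cand))
  df <- df[order(df$unit, df$start), ]
  keep <- rep(TRUE, nrow(df))
  covered <- rep(FALSE, n)
  for (r in seq_len(nrow(df))) {
    span <- df$start[r]:df$end[r]
    if (any(covered[span])) keep[r] <- FALSE else covered[span] <- TRUE
  }
  df <- df[keep, ]
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  df
}

# Brute-force perfect tandem repeat scan over all (start, period).
trOracle <- function(s, minPeriod = 7, maxPeriod = 100, minCopies = 2, minTotal = 26) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  smallestPeriod <- function(m) {
    k <- length(m)
    for (p in seq_len(k)) {
      if (k %% p == 0 && all(m == rep(m[seq_len(p)], k / p))) return(p)
    }
    k
  }
  out <- list()
  for (p in minPeriod:min(maxPeriod, n - 1)) {
    i <- 1L
    while (i + p <= n) {
      if (i > 1L && v[i - 1L] == v[i - 1L + p]) { i <- i + 1L; next }
      j <- i
      while (j + p <= n && v[j] == v[j + p]) j <- j + 1L
      total <- (j - i) + p
      if (total >= max(minTotal, minCopies * p) &&
          smallestPeriod(v[i:(i + p - 1L)]) == p) {
        out[[length(out) + 1L]] <- data.frame(
          start = i, end = i + total - 1L, period = p,
          copy_number = total / p, total_length = total)
      }
      i <- i + 1L
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      period = integer(), copy_number = numeric(),
                                      total_length = integer()))
  df <- unique(do.call(rbind, out))
  df <- df[df$copy_number >= minCopies, ]
  df <- df[order(df$start, df$period), ]
  rownames(df) <- NULL
  df
}

# Exhaustive per-position context labelling from a raw feature table.
contextOracle <- function(positions, featDf, n) {
  exon <- featDf[featDf$kind %in% c("CDS", "tRNA", "rRNA"), ]
  spans <- do.call(rbind, lapply(split(featDf, featDf$gene), function(d)
    data.frame(gene = d$gene[1], start = min(d$start), end = max(d$end))))
  vapply(positions, function(p) {
    hit <- unique(exon$gene[exon$start <= p & exon$end >= p])
    if (length(hit)) return(paste0("CDS:", paste(sort(hit), collapse = "|")))
    hit <- unique(spans$gene[spans$start <= p & spans$end >= p])
    if (length(hit)) return(paste0("intron:", paste(sort(hit), collapse = "|")))
    dl <- (p - spans$end) %% n; dl[dl == 0] <- n
    dr <- (spans$start - p) %% n; dr[dr == 0] <- n
    paste0("intergenic:", spans$gene[which.min(dl)], "-", spans$gene[which.min(dr)])
  }, character(1))
}

# A small panel configuration used by most synthetic-data tests.
smallPanelConfig <- function(seed = 3) {
  simulationConfig(
    seed = seed, genome_length = 40000, ir_length = 3000, ssc_length = 5000,
    n_filler_genes = 0,
    category_counts = c(lineage_ancestral = 30, pimpinellifolium_lineage = 10,
                        de_novo_cultivated = 8, commercial_lineage_specific = 3,
                        local_diagnostic = 2),
    other_counts = c(m82_private = 2, cor_private = 1, cer2_private = 1,
                     pim1_private = 2, pim2_private = 2, pim_pair = 0,
                     cer1_pim_clade = 4, wild_shared = 3),
    ssr_classes = c(ancestral = 10, lineage_shared = 2, local_diagnostic = 1,
                    vlyc_diagnostic = 1, cer2_mixed = 1, m82_mixed = 1,
                    pim_shift = 4),
    n_tr = 4
  )
}

# Toy annotation builder: single-chromosome feature table + object.
toyAnnotation <- function(featDf, n) {
  plastomeAnnotation(featDf, n)
}
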