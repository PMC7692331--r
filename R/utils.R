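#' @import methods
#' @importFrom stats setNames
NULL

# Single source of truth for the DNA complement used across the package.
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Reverse complement of a character string
#'
#' Thin wrapper used internally where sequences travel as plain strings;
#' delegates to [Biostrings::reverseComplement()] for real sequence objects.
#'
#' @param x a single character string over `{A,C,G,T,N}`.
#' @return the reverse-complemented string.
#' @keywords internal
.revcomp <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(rev(unname(.COMPLEMENT[v])), collapse = "")
}

# Complement of a character vector of single bases.
.compVec <- function(v) unname(.COMPLEMENT[v])

# Split a string into a character vector of single bases.
.toVec <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.fromVec <- function(v) paste(v, collapse = "")

# 1-based circular index into [1, n].
.wrap1 <- function(i, n) ((i - 1L) %% n) + 1L

# Length of a 1-based inclusive interval on a circle of size n; start > end
# means the interval wraps through the origin.
.circLen <- function(start, end, n) {
  ifelse(end >= start, end - start + 1L, n - start + 1L + end)
}

# Positions covered by a (possibly wrapping) circular interval.
.circPositions <- function(start, end, n) {
  if (end >= start) seq.int(start, end) else c(seq.int(start, n), seq.int(1L, end))
}

# Smallest period of a motif; motif is primitive iff period == nchar.
# Straightforward divisor scan (n <= 100 in practice).
.primitivePeriod <- function(motif) {
  n <- nchar(motif)
  v <- .toVec(motif)
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    if (all(v == rep(v[seq_len(p)], n %/% p))) return(p)
  }
  n
}

.isPrimitive <- function(motif) .primitivePeriod(motif) == nchar(motif)

# stopifnot() with a formatted message.
.check <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
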