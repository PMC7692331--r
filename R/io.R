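#' Read plastome sequences from a FASTA file
#'
#' Records are upper-cased and `U` is mapped to `T`; any character outside
#' `{A,C,G,T,N}` is an error, as are duplicated or empty records.
#'
#' @param path FASTA file (multi-record, any line wrap).
#' @return a named [Biostrings::DNAStringSet], one entry per genotype.
#' @export
readPlastomes <- function(path) {
  .check(file.exists(path), "file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  .check(length(dup) == 0L, "duplicate sequence id: %s", paste(unique(dup), collapse = ", "))
  seqs <- chartr("Uu", "Tt", toupper(as.character(raw)))
  .check(all(nchar(seqs) > 0L), "empty record: %s",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- unique(.toVec(gsub("[ACGTN]", "", paste(seqs[bad], collapse = ""))))
    stop(sprintf("invalid characters in %s: %s",
                 paste(ids[bad], collapse = ", "), paste(ch, collapse = " ")),
         call. = FALSE)
  }
  out <- DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write plastome sequences to FASTA
#'
#' @param seqs named [Biostrings::DNAStringSet].
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
writePlastomes <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read an aligned FASTA into a PlastomeAlignment
#'
#' @param path aligned FASTA; rows must have equal width over
#'   `{A,C,G,T,N,-}`.
#' @param referenceId name of the reference row.
#' @return a [PlastomeAlignment-class].
#' @export
readAlignment <- function(path, referenceId) {
  .check(file.exists(path), "file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  rows <- chartr("Uu", "Tt", toupper(as.character(raw)))
  .check(!any(grepl("[^ACGTN-]", rows)), "alignment rows restricted to A,C,G,T,N,-")
  names(rows) <- ids
  plastomeAlignment(rows, referenceId)
}

#' Write a PlastomeAlignment as aligned FASTA
#' @param msa a [PlastomeAlignment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(msa, path) {
  Biostrings::writeXStringSet(msa@aln, path)
  invisible(path)
}

# ---- annotation ------------------------------------------------------------

# Build the internal feature GRanges from a per-interval data.frame and
# enforce the FeatureAnnotation invariants.
.makeAnnotation <- function(df, genomeLength) {
  need <- c("feature_id", "gene", "kind", "start", "end", "strand", "phase", "exon_rank")
  .check(all(need %in% names(df)), "annotation table needs columns: %s",
         paste(need, collapse = ", "))
  .check(all(df$start >= 1L & df$end <= genomeLength & df$start <= df$end),
         "every feature interval must lie within [1, %d]", genomeLength)
  # gene span rows derived for genes that lack one
  for (g in unique(df$gene)) {
    rows <- df[df$gene == g, , drop = FALSE]
    if (!any(rows$kind == "gene")) {
      df <- rbind(df, data.frame(
        feature_id = paste0("gene:", g), gene = g, kind = "gene",
        start = min(rows$start), end = max(rows$end),
        strand = rows$strand[1L], phase = 0L, exon_rank = 1L,
        stringsAsFactors = FALSE
      ))
    }
  }
  translatable <- rep(NA, nrow(df))
  for (fid in unique(df$feature_id[df$kind == "CDS"])) {
    sel <- df$feature_id == fid
    len <- sum(df$end[sel] - df$start[sel] + 1L)
    ok <- (len - df$phase[sel][which.min(df$exon_rank[sel])]) %% 3L == 0L
    if (!ok) warning(sprintf("CDS %s length not divisible by 3 after phase; flagged non-translatable", fid))
    translatable[sel] <- ok
    # intervals of one CDS must not overlap
    o <- order(df$start[sel])
    s <- df$start[sel][o]; e <- df$end[sel][o]
    .check(all(s[-1L] > e[-length(e)]), "intervals of CDS %s overlap", fid)
  }
  gr <- GRanges("plastome", IRanges(df$start, df$end), strand = df$strand)
  mcols(gr)$feature_id <- df$feature_id
  mcols(gr)$gene <- df$gene
  mcols(gr)$kind <- df$kind
  mcols(gr)$phase <- as.integer(df$phase)
  mcols(gr)$exon_rank <- as.integer(df$exon_rank)
  mcols(gr)$translatable <- translatable
  new("PlastomeAnnotation", features = gr, genomeLength = as.integer(genomeLength))
}

#' Construct a PlastomeAnnotation from a feature table
#'
#' @param df data.frame with columns `feature_id`, `gene`, `kind` (`gene`,
#'   `CDS`, `tRNA`, `rRNA`), `start`, `end` (1-based inclusive), `strand`
#'   (`+`/`-`), `phase` (0/1/2) and `exon_rank` (interval rank in translation
#'   order; spliced CDS share a `feature_id`).
#' @param genomeLength length of the circular genome.
#' @return a [PlastomeAnnotation-class]. CDS whose summed length is not
#'   divisible by 3 after phase adjustment raise a warning and are flagged
#'   non-translatable.
#' @export
plastomeAnnotation <- function(df, genomeLength) .makeAnnotation(df, genomeLength)

#' Read a GFF3 annotation
#'
#' Understands the subset of GFF3 used for plastome annotations: `gene`
#' features plus `CDS`, `tRNA` and `rRNA` features tied to their gene via
#' `Parent` (or sharing an `ID` across the intervals of one spliced CDS).
#' Coordinates are 1-based inclusive per the GFF3 specification.
#'
#' @param path GFF3 file.
#' @param genomeLength genome length; defaults to the
#'   `##sequence-region` pragma when present.
#' @return a [PlastomeAnnotation-class].
#' @export
readAnnotationGff <- function(path, genomeLength = NULL) {
  .check(file.exists(path), "file not found: %s", path)
  if (is.null(genomeLength)) {
    head_ <- readLines(path, n = 50L)
    sr <- grep("^##sequence-region", head_, value = TRUE)
    .check(length(sr) > 0L, "genomeLength not given and no ##sequence-region pragma in %s", path)
    genomeLength <- as.integer(strsplit(trimws(sr[1L]), "\\s+")[[1L]][4L])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  m <- mcols(gr)
  type <- as.character(m$type)
  keep <- type %in% c("gene", "CDS", "tRNA", "rRNA")
  gr <- gr[keep]; m <- mcols(gr); type <- type[keep]
  getCol <- function(nm) {
    if (nm %in% colnames(m)) as.character(m[[nm]]) else rep(NA_character_, length(gr))
  }
  ids <- getCol("ID")
  names_ <- getCol("Name")
  geneAttr <- getCol("gene")
  parents <- if ("Parent" %in% colnames(m)) {
    vapply(as.list(m$Parent), function(p)
      if (length(p)) as.character(p)[1L] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  geneName <- function(i) {
    # prefer explicit gene= attribute, then the parent gene's Name/ID, then own Name/ID
    if (!is.na(geneAttr[i])) return(geneAttr[i])
    if (!is.na(parents[i])) {
      j <- which(ids == parents[i])
      if (length(j)) {
        j <- j[1L]
        if (!is.na(geneAttr[j])) return(geneAttr[j])
        if (!is.na(names_[j])) return(names_[j])
      }
      return(sub("^gene:", "", parents[i]))
    }
    if (!is.na(names_[i])) return(names_[i])
    if (!is.na(ids[i])) return(sub("^(gene|cds):", "", ids[i]))
    paste0("feature", i)
  }
  phase <- if ("phase" %in% colnames(m)) {
    suppressWarnings(as.integer(as.character(m$phase)))
  } else rep(NA_integer_, length(gr))
  phase[is.na(phase)] <- 0L
  rows <- lapply(seq_along(gr), function(i) {
    fid <- if (!is.na(ids[i])) ids[i] else paste0(type[i], ":", geneName(i))
    str <- as.character(strand(gr))[i]
    data.frame(
      feature_id = fid, gene = geneName(i), kind = type[i],
      start = start(gr)[i], end = end(gr)[i],
      strand = if (str %in% c("+", "-")) str else "+",
      phase = phase[i], exon_rank = 1L, stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  # translation-order ranks for spliced CDS sharing one ID
  for (fid in unique(df$feature_id[df$kind == "CDS"])) {
    sel <- which(df$feature_id == fid)
    if (length(sel) > 1L) {
      asc <- order(df$start[sel])
      if (df$strand[sel][1L] == "-") asc <- rev(asc)
      df$exon_rank[sel[asc]] <- seq_along(sel)
      # codon start phase lives on the first interval in translation order
      df$phase[sel] <- df$phase[sel[asc][1L]]
    }
  }
  .makeAnnotation(df, genomeLength)
}

#' Write a PlastomeAnnotation as GFF3
#'
#' @param ann a [PlastomeAnnotation-class].
#' @param path output file.
#' @param seqid sequence name for column 1.
#' @return `path`, invisibly.
#' @export
writeAnnotationGff <- function(ann, path, seqid = "plastome") {
  gr <- ann@features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", seqid, ann@genomeLength)), con)
  m <- mcols(gr)
  ord <- order(m$kind != "gene", start(gr), m$exon_rank)
  for (i in ord) {
    kind <- m$kind[i]
    attrs <- if (kind == "gene") {
      sprintf("ID=%s;Name=%s", m$feature_id[i], m$gene[i])
    } else {
      sprintf("ID=%s;Parent=gene:%s;gene=%s", m$feature_id[i], m$gene[i], m$gene[i])
    }
    phase <- if (kind == "CDS") as.character(m$phase[i]) else "."
    writeLines(sprintf("%s\tplastomeVar\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                       seqid, kind, start(gr)[i], end(gr)[i],
                       as.character(strand(gr)[i]), phase, attrs), con)
  }
  invisible(path)
}

# ---- group scheme files ----------------------------------------------------

#' Read a group-scheme file
#'
#' Plain three-column whitespace-separated text: genotype id, group label (or
#' `PANEL` for distant-panel members), and a 0/1 reference flag.
#'
#' @param path scheme file.
#' @param groupLevels ordered group labels (defaults as in [groupScheme()]).
#' @return a [GroupScheme-class].
#' @export
readGroupScheme <- function(path, groupLevels = c("var_lycopersicum",
                                                  "local_accessions",
                                                  "var_cerasiforme",
                                                  "pimpinellifolium",
                                                  "wild_close")) {
  .check(file.exists(path), "file not found: %s", path)
  df <- read.table(path, header = FALSE, col.names = c("genotype", "group", "ref"),
                   stringsAsFactors = FALSE, comment.char = "#")
  inPanel <- df$group == "PANEL"
  groups <- setNames(df$group[!inPanel], df$genotype[!inPanel])
  groupScheme(groups, df$genotype[inPanel], df$genotype[df$ref == 1L][1L],
              groupLevels = groupLevels)
}

#' Write a GroupScheme to a scheme file
#' @param scheme a [GroupScheme-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGroupScheme <- function(scheme, path) {
  ids <- c(names(scheme@groups), scheme@distantPanel)
  grp <- c(unname(scheme@groups), rep("PANEL", length(scheme@distantPanel)))
  writeLines(sprintf("%s\t%s\t%d", ids, grp, as.integer(ids == scheme@referenceId)), path)
  invisible(path)
}
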