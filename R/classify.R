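#' Group allele states of one variant site
#'
#' For each group of the scheme, the state is `REF` when every non-missing
#' member carries the reference allele, `ALT` when every non-missing member
#' carries one identical non-reference allele, `MIXED` when at least two
#' distinct non-missing alleles occur, and `MISSING` when all members are
#' missing. The distant panel gets the same treatment (`panel_state`).
#'
#' @param alleles named character vector, genotype id -> allele (`NA` =
#'   missing); must cover every genotype of the scheme.
#' @param refAllele the reference allele at the site.
#' @param scheme a [GroupScheme-class].
#' @return list with `states` (named character per group), `alt` (the shared
#'   alternative allele per group, `NA` unless state is `ALT`),
#'   `panel_state`, `panel_alt` and `ref`.
#' @export
groupStates <- function(alleles, refAllele, scheme) {
  stopifnot(is(scheme, "GroupScheme"))
  ids <- genotypeIds(scheme)
  .check(all(ids %in% names(alleles)),
         "alleles missing for genotypes: %s",
         paste(setdiff(ids, names(alleles)), collapse = ", "))
  stateOf <- function(members) {
    a <- alleles[members]
    a <- a[!is.na(a)]
    if (length(a) == 0L) return(c("MISSING", NA))
    u <- unique(a)
    if (length(u) > 1L) return(c("MIXED", NA))
    if (u == refAllele) c("REF", NA) else c("ALT", u)
  }
  states <- character(0); alts <- character(0)
  for (g in scheme@groupLevels) {
    st <- stateOf(names(scheme@groups)[scheme@groups == g])
    states[g] <- st[1L]; alts[g] <- st[2L]
  }
  pst <- stateOf(scheme@distantPanel)
  list(states = states, alt = alts, panel_state = pst[1L], panel_alt = pst[2L],
       ref = refAllele)
}

#' Polarize a variant against the distant outgroup panel
#'
#' The derived allele is the allele absent from the panel's non-missing
#' alleles; when the panel carries several of the site's alleles, or is
#' entirely missing, the site is `UNPOLARIZED`.
#'
#' @param alleles named allele vector as in [groupStates()].
#' @param panelIds genotype ids of the distant panel (non-empty).
#' @return the derived allele, or `"UNPOLARIZED"`.
#' @export
polarizeAllele <- function(alleles, panelIds) {
  .check(length(panelIds) > 0L, "distant panel must be non-empty")
  all_ <- unique(alleles[!is.na(alleles)])
  pan <- unique(alleles[panelIds][!is.na(alleles[panelIds])])
  if (length(pan) == 0L) return("UNPOLARIZED")
  absent <- setdiff(all_, pan)
  if (length(absent) == 1L) absent else "UNPOLARIZED"
}

#' Classify a group-state vector into an allele-sharing category
#'
#' Mutually exclusive categories, evaluated in order (the order is the
#' documented tie-break; the reference genotype sits in `var_lycopersicum`,
#' so the shared cultivated allele is `REF`):
#'
#' 1. `lineage_ancestral` - all five groups `REF`, panel `ALT` (with
#'    `strictPanel = FALSE`, panel `MIXED` also accepted).
#' 2. `pimpinellifolium_lineage` - first four groups `REF`, `wild_close`
#'    `MIXED` or `ALT`, panel `ALT` or `MIXED`.
#' 3. `de_novo_cultivated` - `var_lycopersicum`/`local` `REF`, `cerasiforme`
#'    `MIXED`, `pimpinellifolium` `ALT`, panel `ALT` or `MIXED` (the panel
#'    condition keeps sites whose derived allele arose on the
#'    cerasiforme/pimpinellifolium side, where the panel matches the
#'    cultivated allele, out of this de novo class).
#' 4. `commercial_lineage_specific` - `var_lycopersicum` `REF`, `local`
#'    `ALT`, `cerasiforme` `MIXED` or `REF`, `pimpinellifolium` `ALT`
#'    carrying the same allele as `local` (checked when allele information is
#'    available), `wild_close` `ALT`.
#' 5. `local_diagnostic` - `local` `ALT`, all other groups `REF`.
#' 6. `other` - anything else.
#'
#' @param states named character vector of group states, in the order of the
#'   scheme's `groupLevels` (var_lycopersicum, local_accessions,
#'   var_cerasiforme, pimpinellifolium, wild_close).
#' @param panelState state of the distant panel.
#' @param alt optional named vector of shared ALT alleles per group (from
#'   [groupStates()]); enables the rule-4 same-allele check.
#' @param strictPanel rule 1 requires a fixed-`ALT` panel when `TRUE`
#'   (default); `MIXED` also accepted when `FALSE`.
#' @return one category label.
#' @export
classifyPattern <- function(states, panelState, alt = NULL, strictPanel = TRUE) {
  v <- unname(states)
  .check(length(v) == 5L, "expected states for exactly five groups")
  V <- v[1L]; L <- v[2L]; C <- v[3L]; P <- v[4L]; W <- v[5L]
  if (all(v == "REF") && panelState == "REF")
    stop("not a variant: all groups and the panel carry the reference allele",
         call. = FALSE)
  panelAlt1 <- if (strictPanel) panelState == "ALT" else panelState %in% c("ALT", "MIXED")
  if (all(v == "REF") && panelAlt1) return("lineage_ancestral")
  if (V == "REF" && L == "REF" && C == "REF" && P == "REF" &&
      W %in% c("MIXED", "ALT") && panelState %in% c("ALT", "MIXED"))
    return("pimpinellifolium_lineage")
  if (V == "REF" && L == "REF" && C == "MIXED" && P == "ALT" &&
      panelState %in% c("ALT", "MIXED"))
    return("de_novo_cultivated")
  if (V == "REF" && L == "ALT" && C %in% c("MIXED", "REF") && P == "ALT" &&
      W == "ALT") {
    sameAllele <- is.null(alt) || is.na(alt[2L]) || is.na(alt[4L]) ||
      alt[2L] == alt[4L]
    if (sameAllele) return("commercial_lineage_specific")
  }
  if (L == "ALT" && V == "REF" && C == "REF" && P == "REF" && W == "REF")
    return("local_diagnostic")
  "other"
}

#' Category labels used by the sharing-pattern classifier
#' @return character vector of the six category labels.
#' @export
variantCategories <- function() {
  c("lineage_ancestral", "pimpinellifolium_lineage", "de_novo_cultivated",
    "commercial_lineage_specific", "local_diagnostic", "other")
}

#' Classify all SNP sites of a panel
#'
#' Computes group states, polarizes against the distant panel and assigns
#' each site a sharing-pattern category.
#'
#' @param vp a [VariantPanel-class].
#' @param scheme a [GroupScheme-class] covering the panel's genotypes.
#' @param strictPanel see [classifyPattern()].
#' @return list with `classification` (data.frame: `position`, one
#'   `state_<group>` column per group, `panel_state`, `category`,
#'   `derived_allele`) and `counts` (named integer vector over
#'   [variantCategories()]).
#' @export
classifyVariants <- function(vp, scheme, strictPanel = TRUE) {
  stopifnot(is(vp, "VariantPanel"), is(scheme, "GroupScheme"))
  nSites <- nrow(vp@sites)
  glv <- scheme@groupLevels
  stateM <- matrix(NA_character_, nrow = nSites, ncol = length(glv) + 1L,
                   dimnames = list(NULL, c(glv, "panel")))
  category <- character(nSites)
  derived <- character(nSites)
  panelIds <- scheme@distantPanel
  for (i in seq_len(nSites)) {
    al <- vp@alleles[, i]
    gs <- groupStates(al, vp@sites$ref[i], scheme)
    stateM[i, ] <- c(gs$states, gs$panel_state)
    category[i] <- classifyPattern(gs$states, gs$panel_state, gs$alt,
                                   strictPanel = strictPanel)
    derived[i] <- polarizeAllele(al, panelIds)
  }
  cls <- data.frame(position = vp@sites$position, stringsAsFactors = FALSE)
  for (g in glv) cls[[paste0("state_", g)]] <- stateM[, g]
  cls$panel_state <- stateM[, "panel"]
  cls$category <- category
  cls$derived_allele <- derived
  counts <- setNames(integer(length(variantCategories())), variantCategories())
  tab <- table(category)
  counts[names(tab)] <- as.integer(tab)
  list(classification = cls, counts = counts)
}

#' Classify SSR loci by repeat-count sharing pattern
#'
#' Per locus, each group's state is its uniform repeat count or `MIXED`;
#' categories, in order: `ancestral_shared` (one count across every genotype
#' including the distant panel), `group_diagnostic:<group>` (that group
#' uniform at a count no other genotype has), `lineage_pattern` (the
#' count-states match one of SNP rules 1-4 with the reference genotype's
#' count playing the reference-allele role), else `other`.
#'
#' @param ssr an [SsrTable-class].
#' @param scheme a [GroupScheme-class].
#' @return data.frame with one row per locus: `ref_start`, `motif`,
#'   `category`, `polymorphic`.
#' @export
classifySsrPatterns <- function(ssr, scheme) {
  stopifnot(is(ssr, "SsrTable"), is(scheme, "GroupScheme"))
  ids <- genotypeIds(scheme)
  .check(all(ids %in% rownames(ssr@counts)),
         "SSR table missing genotypes of the scheme")
  refId <- scheme@referenceId
  out <- character(ncol(ssr@counts))
  for (li in seq_len(ncol(ssr@counts))) {
    cnt <- ssr@counts[ids, li]
    nonNA <- cnt[!is.na(cnt)]
    if (length(unique(nonNA)) == 1L && length(nonNA) == length(ids)) {
      out[li] <- "ancestral_shared"
      next
    }
    diag <- NA_character_
    for (g in scheme@groupLevels) {
      members <- names(scheme@groups)[scheme@groups == g]
      a <- cnt[members]; a <- a[!is.na(a)]
      if (length(a) == 0L || length(unique(a)) != 1L) next
      others <- cnt[setdiff(ids, members)]
      if (!any(others == a[1L], na.rm = TRUE)) { diag <- g; break }
    }
    if (!is.na(diag)) {
      out[li] <- paste0("group_diagnostic:", diag)
      next
    }
    # SNP-rule analogy on count states, reference count = reference genotype's
    refCnt <- cnt[refId]
    pseudo <- ifelse(is.na(cnt), NA_character_, as.character(cnt))
    gs <- groupStates(pseudo, as.character(refCnt), scheme)
    cat_ <- tryCatch(
      classifyPattern(gs$states, gs$panel_state, gs$alt),
      error = function(e) "other"
    )
    out[li] <- if (cat_ %in% c("lineage_ancestral", "pimpinellifolium_lineage",
                               "de_novo_cultivated", "commercial_lineage_specific"))
      "lineage_pattern" else "other"
  }
  data.frame(
    ref_start = ssr@loci$ref_start,
    motif = ssr@loci$motif,
    category = out,
    polymorphic = ssr@loci$polymorphic,
    stringsAsFactors = FALSE
  )
}
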