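---
title: "Comparative plastome variability: models, conventions and design choices"
author: "plastomeVar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome variability: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeVar)
```

## The problem this package addresses

Chloroplast genomes (plastomes) are uniparentally inherited, essentially
non-recombining, and slowly evolving, which makes them sensitive recorders of
demographic events such as domestication bottlenecks. A typical study design
compares ~20 complete plastomes of a crop and its wild relatives: cultivated
varieties and landraces, the closest wild ancestor, a handful of closely
related wild species, and a panel of distantly related wild species used to
polarize alleles. The questions are always the same: how much variation
survives in the cultivated gene pool, which alleles are ancestral versus
de novo, which variants diagnose particular groups, and whether the phylogeny
is consistent with a single domestication origin.

`plastomeVar` implements that analysis as a reusable pipeline: quadripartite
structure detection, SNP/indel extraction from a multiple sequence alignment
(MSA), microsatellite (SSR) and perfect tandem repeat (TR) haplotyping,
allele-sharing classification, bottleneck statistics, and a distance-based
phylogeny — together with a synthetic panel generator that plants all of the
above with known truth, so every stage is testable without any external data.

## Quadripartite structure

A plastome is circular with two identical inverted repeats (IRa/IRb)
separating a large and a small single-copy region (LSC/SSC).
`detectQuadripartite()` searches the circular sequence for the longest pair
of non-overlapping, exact, maximal inverted repeats (default minimum arm
1,000 bp) using 25-mer seeds against the reverse complement, grouped by
diagonal and extended to maximal runs. The larger single-copy gap is labeled
LSC and `IRa` is the copy that follows the LSC in circular order. Exact-match
arms are assumed because assembled plastome IR copies are normally identical;
near-identical IRs are out of scope. The defining identity
`lsc + ssc + 2*ir = total` is enforced by the class validity and detection is
rotation invariant. A sequence whose best repeat pair overlaps itself (a
degenerate palindrome) is rejected rather than misreported.

## SNPs and indels from the MSA

All variant calling is alignment-based, relative to a designated reference
genotype. Conventions, chosen once and used everywhere:

* Coordinates are 1-based inclusive in every report and file (GFF/VCF
  convention); alignment columns map to reference coordinates through the
  cumulative count of non-gap reference bases, and columns where the
  reference is gapped anchor insertions "after position p".
* A column is a SNP site iff the reference base is `A/C/G/T` and at least two
  distinct `A/C/G/T` bases occur in the column. Gaps and `N` are *missing*:
  they never create a SNP and never suppress one. Multiallelic columns count
  once (site-based counting).
* Maximal runs of columns sharing one gap pattern become single indel events;
  an insertion whose bases equal the adjacent reference flank of the same
  length is flagged as a tandem duplication.
* A run of all-gap reference columns longer than half the alignment aborts
  the extraction: such an alignment is broken, and silently renumbering
  coordinates against it would poison every downstream table.

Coding effects are computed per site by strand-aware codon reconstruction
from the spliced CDS intervals, translated with the bacterial/plastid code
(table 11) without initiator-codon special-casing. Only the focal allele is
substituted; haplotype-aware codon reconstruction (two co-occurring changes
in one codon) is a documented limitation. tRNA/rRNA exons count as "coding
sequence" for context tallies but never receive amino-acid calls.

## SSRs and tandem repeats

SSR detection reports maximal perfect runs of a primitive 1-6 bp motif at
the MISA-style thresholds 1/8, 2/6, 3/5, 4/5, 5/5, 6/5 (unit size / minimum
units). A run qualifying at several unit sizes is reported only for its
primitive motif, and overlapping reports resolve in favour of the smaller
unit. Motifs are canonicalized to the lexicographically smallest rotation of
the primitive root; strands are deliberately not collapsed, because repeat
counts are scored per genotype on the published strand.

Cross-genotype haplotyping projects each genome's detections onto reference
coordinates through the MSA, merges loci whose projected intervals overlap
with matching canonical motifs, and then *recounts* every genotype's units
from its own ungapped sequence at the locus. The recount is what makes
one-unit differences robust: a genotype one unit below the detection
threshold is still scored.

Perfect TRs use period 7-100 bp, at least 2 copies and at least 26 bp total,
reported at the smallest period; the period floor of 7 keeps TR space
disjoint from SSR space. These thresholds are configurable; the defaults
were chosen so that a perfect-repeat definition covers the 13-26 bp period
range typical of plastome TR surveys. Score-based detectors (alignment-scored
imperfect arrays) are out of scope.

## Allele-sharing classification

For each SNP site, each group of the five-group scheme receives a state:
`REF` (all non-missing members carry the reference allele), `ALT` (one
identical non-reference allele), `MIXED`, or `MISSING`. The distant panel is
summarized the same way. Categories are assigned by the first matching rule:

1. **lineage_ancestral** — all five groups `REF`, panel `ALT`: the shared
   cultivated-lineage allele is derived relative to the distant wild species.
2. **pimpinellifolium_lineage** — the four cultivated/ancestor groups `REF`,
   the close-wild group `ALT` or `MIXED`, panel not `REF`: fixed on the
   lineage joining the wild ancestor and the cultivated material.
3. **de_novo_cultivated** — commercial and local groups `REF`, cerasiforme
   `MIXED`, pimpinellifolium `ALT`, **panel `ALT` or `MIXED`**: arose after
   the split from the wild ancestor, with the cherry-tomato group straddling
   the split. The panel condition is essential: without it, a site whose
   derived allele arose on the cerasiforme/pimpinellifolium side (panel
   matching the cultivated allele) would be mislabeled de novo even though
   the cultivated allele is the ancestral one.
4. **commercial_lineage_specific** — commercial varieties `REF` against a
   shared non-reference allele in local accessions, the wild ancestor and
   close wild species (same allele in local and ancestor when allele
   information is available).
5. **local_diagnostic** — local accessions `ALT`, everything else `REF`.
6. **other** — anything else (private mutations, within-group variation,
   lineage-internal patterns).

Rule order is the documented tie-break; an all-`REF` vector with an all-`REF`
panel is "not a variant" and errors. Polarization returns the allele absent
from the panel's non-missing alleles, or `UNPOLARIZED` when the panel is
uninformative. Rule 1 by default demands a fixed (`ALT`) panel; a `MIXED`
panel can be accepted via `strictPanel = FALSE` since "different from the
distant wild species" is ambiguous about panel fixity.

SSR loci are classified analogously on repeat counts: `ancestral_shared`
(one count across all genotypes including the panel), `group_diagnostic:<g>`
(group g uniform at a count nobody else carries), `lineage_pattern` (count
states matching rules 1-4 with the reference genotype's count in the
reference role), else `other`.

## Bottleneck statistics

`polymorphicInSubset()` counts loci with at least two distinct non-missing
alleles (or repeat counts) among subset members; fractions are percentages
of the full-panel locus total, reported to one decimal.
`sharedWithGroup()` counts loci with one uniform allele across the union of
two disjoint subsets. `foldRatio()` rounds to the nearest integer. The
default cultivated subset is commercial varieties + local accessions + the
cerasiforme group *without its first member*: one cherry-tomato accession
behaves like a wild genotype (it carries the ancestor's alleles at the
de novo sites and resolves inside the ancestor's clade), and including it
would conflate within-cultivated polymorphism with the cultivated/wild
split. Missing alleles never count toward polymorphism.

## Phylogeny

Distances are p-distances over columns where both rows carry `A/C/G/T`.
Trees are neighbor-joining (via `ape`); negative branch lengths are clamped
to zero with the deficit moved to the sibling branch; an all-zero matrix
yields a star tree. Bootstrap support resamples alignment columns with
replacement (replicate *r* seeded with `seed + r`); because invariant
gap-free columns only contribute to denominators, replicates are computed
from resampling weights on the informative columns plus a single weight for
the invariant remainder — numerically identical to naive resampling, and
verified against a naive implementation in the tests. Support is the
percentage of replicates containing each original internal bipartition.

One artifact worth knowing: groups of *identical* sequences (distance 0) are
resolved by NJ's deterministic tie-break into arbitrary zero-length
branchings, which then reappear in every replicate and can show 100%
support. Interpret support on zero-length branches as a tie artifact, not as
signal; the tests only assert supports on branches with planted signal.

## The synthetic panel generator

`simulatePanel()` is first-class, tested code, not a fixture. Its defaults
are the study conditions used across the tests: a 155,000 bp circular
genome (LSC 85,400, SSC 18,400, IR 25,600), 21 genotypes (2 commercial
varieties including the reference, 7 local accessions, 2 cherry-tomato
accessions, 2 wild-ancestor accessions, 3 close wild species, 5 distant
panel species), 454 SNP sites with category counts 271/90/38/5/2 plus 48
"other" sites (private mutations of single genotypes, a 10-site split
between the two ancestor accessions, an 18-site cherry+ancestor stem class,
and 11 convergent wild-shared sites), 114 SSR loci (67 ancestral, 74 shared
with the ancestor, 12 polymorphic among cultivated, 47 among wild), 17
perfect TRs with periods 13-26, one 1-bp deletion private to the third
local accession, and one `(ATAA)2` duplication private to the local
accessions. 42 SNPs are planted in a `ycf1`-like gene (including a
nonsynonymous local-diagnostic site) and 9 synonymous ones at
fourfold-degenerate third positions of an `ndhH`-like gene. These joint
counts are mutually consistent by construction — each planted pattern class
was checked against every statistic it touches — and generation is a pure
function of the configuration, so any seed reproduces them exactly.

Mutation patterns are consistent with a fixed species tree (distant clade;
close-wild species basal to the cultivated side; the first cherry accession
attached beside the ancestor pair; the second inside the cultivated clade).
The 11 convergent wild-shared sites are the one deliberate exception: they
require two origins on that tree and are planted as explicit allele patterns
with truth category "other".

What the generator does *not* emulate, and hence what passing tests do not
show about real data: aligner errors (the emitted MSA is the true one),
sequencing or assembly artifacts, rate heterogeneity and multiple hits,
variation inside the inverted repeats (all planted variation is single-copy,
so each simulated genome keeps identical IRs), imperfect or compound
repeats, and heteroplasmy. Results on real panels inherit whatever error the
upstream aligner introduces.

Numerical hygiene in generation: planted repeat arrays get flank guards so
chance bases cannot extend them; a scrub loop mutates accidental background
repeats until the detectors report exactly the planted set, mirroring any
fix that lands inside an IR into the partner copy; the four region junctions
are guarded so the IR pair cannot extend by chance; SNP alternative alleles
avoid the two neighbouring bases on each side so substitutions cannot spawn
new repeat runs.

## Problem sizes used by the test suite

Unit and property tests run on 40 kb panels (scaled gene roster, 59 planted
sites, 20 SSR loci); oracle comparisons use 2 kb sequences (200 random
sequences for repeat detection, 50 random configurations for structure
detection); the acceptance checks run the full default panel once with fixed
seeds and 100 bootstrap replicates. The whole suite completes in a few
minutes on one CPU.

## Known limitations

* Exact-arm IR detection only; IR boundary "contraction/expansion" analyses
  need near-identical repeat handling that is out of scope.
* One-site-at-a-time effect annotation; no haplotype-aware codons.
* The SSR merging rule (overlapping projected intervals + matching canonical
  motif) is this package's definition; published union counts from other
  tools may differ at loci that drift apart in the alignment.
* NJ + p-distance is a deliberate substitute for likelihood tree inference:
  for panels of near-identical plastomes the topology signal is carried by
  fixed differences, and the acceptance checks are on topology and support,
  not on likelihoods or branch lengths.
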