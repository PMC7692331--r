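# plastomeVar

Comparative variability analysis of complete chloroplast genomes
(plastomes) across a panel of related genotypes — built for domestication
studies that ask how much cytoplasmic diversity survives in a crop relative
to its wild relatives, which alleles are ancestral versus de novo, and which
variants diagnose particular groups of accessions.

The package is aimed at plant geneticists who have a multiple sequence
alignment of ~20 complete plastomes (a reference cultivar, landraces, the
closest wild ancestor, close wild species, and a distant-wild outgroup
panel) and want the whole analysis — structure, variants, repeats,
classification, statistics, tree — reproducible from code.

## What it computes

* **Quadripartite structure** — the LSC/SSC/IRa/IRb partition, found as the
  longest pair of non-overlapping exact maximal inverted repeats on the
  circular sequence; the identity `lsc + ssc + 2·ir = total` always holds.
* **SNPs and indels** — extracted from the MSA against a reference
  genotype; gaps and `N` are missing (never alleles); maximal gap-pattern
  runs become indel events, with tandem-duplication insertions flagged;
  coding effects by strand-aware codon substitution under translation
  table 11.
* **SSR / tandem-repeat haplotypes** — perfect microsatellites at MISA-style
  thresholds (1/8, 2/6, 3/5, 4/5, 5/5, 6/5), merged across genotypes on
  reference coordinates and *recounted* per genotype so one-unit
  differences below the detection threshold are still scored; perfect TRs
  (period 7–100 bp, ≥ 2 copies, ≥ 26 bp).
* **Allele-sharing categories** — per-site group states (`REF`/`ALT`/
  `MIXED`/`MISSING`) over a five-group scheme, polarized against the
  distant panel, classified as `lineage_ancestral`,
  `pimpinellifolium_lineage`, `de_novo_cultivated`,
  `commercial_lineage_specific`, `local_diagnostic`, or `other`.
* **Bottleneck statistics** — polymorphic counts and fractions per genotype
  subset, shared-allele fractions between subsets, fold ratios, per-gene
  and per-context tallies.
* **Phylogeny** — neighbor-joining on p-distances with column-bootstrap
  support and monophyly checks after outgroup rooting.
* **Synthetic panels** — `simulatePanel()` generates a full plastome panel
  with planted, classified variation and truth tables, so every stage is
  verifiable end to end without downloading anything.

## Worked example

```r
library(plastomeVar)

panel <- simulatePanel(simulationConfig(seed = 1))
panel
#> SimulatedPanel: 21 genotypes, 155000 bp reference
#>   planted SNP sites: 454
#>   planted SSR loci:  114
#>   planted TR loci:   17

vp <- extractVariants(panel@alignment, ann = panel@annotation,
                      structure = panel@structure)
vp
#> VariantPanel: 454 SNP sites, 51 indel events across 21 genotypes; reference: IPA6

classifyVariants(vp, panel@scheme)$counts
#>           lineage_ancestral    pimpinellifolium_lineage
#>                         271                          90
#>          de_novo_cultivated commercial_lineage_specific
#>                          38                           5
#>            local_diagnostic                       other
#>                           2                          48

cult <- c("IPA6","M82","cor","pds","pgl","pol","ves2001","vfr","vpz","cer2")
polymorphicInSubset(vp, cult)
#>    count fraction    total
#>     16.0      3.5    454.0

ssr <- buildSsrLocusTable(panel@alignment)
polymorphicInSubset(ssr, cult)
#>    count fraction    total
#>     12.0     10.5    114.0

sharedWithGroup(vp, cult, c("pim1", "pim2"))
#>    count fraction    total
#>    361.0     79.5    454.0

regionLengths(detectQuadripartite(as.character(panel@sequences[["IPA6"]])))
#>  total    lsc    ssc    ira    irb
#> 155000  85400  18400  25600  25600
```

Reading the numbers: of 454 SNP sites across the whole panel, only 16
(3.5%) vary within the cultivated subset — the signature of a severe
cytoplasmic bottleneck — while 361 (79.5%) are uniform and identical across
the cultivated genotypes and the wild ancestor pair. The 271 sites in
`lineage_ancestral` are fixed across all five in-groups and differ from the
distant panel, 38 are de novo mutations of the cultivated lineage, and 2
diagnose the local accessions alone.

`runFullPipeline()` strings all stages together and writes per-stage TSV /
VCF / BED / Newick outputs plus a plain-text report; a thin command-line
wrapper is provided in `inst/scripts/plastome-pipeline.R`.

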