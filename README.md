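# svload

Population-genetic analysis of structural variants (SVs) — deletions,
duplications and inversions — genotyped from short-read data in small,
pedigree-structured populations, with a focus on what inbreeding and
immigration do to the genetic load such variants carry.

Small isolated populations lose diversity by drift and expose recessive
deleterious alleles through inbreeding; immigration ("genetic rescue")
can reverse both.  These processes have mostly been quantified with
SNPs.  `svload` provides the corresponding toolkit for SV genotypes:
the stringent filtering such calls need, pedigree- and PCA-based
validation, annotation and outgroup polarization, and the load and
rescue statistics themselves.  It is aimed at conservation and
population genomicists working with smoove/duphold-style SV call sets
in species with a known founding history.

## What it computes

For a cohort of individuals genotyped at SV loci:

* **Filter cascade** — quality thresholds (deletions `DHFFC < 0.7`,
  duplications `DHFFC > 1.3`, all variants `MSHQ ≥ 3`), a
  genotype-frequency filter (≥ *m* individuals of each genotype,
  default 2), and externalized curation decisions, with per-type
  bookkeeping at every stage.
* **Validation** — trio concordance with Mendelian inheritance
  (15 of the 27 ordered genotype triples are consistent), and PCA of
  genotype dosages with a separation score that flags sequencing-batch
  artifacts in rejected calls.
* **Annotation** — single-category gene overlap (`ENCLOSING` >
  `PARTIAL_CDS` > `NONCODING` > `INTERGENIC`), per-base repeat
  composition (each base counted once), and length spectra with
  peak composition (e.g. SINE content of a ~190 bp deletion peak).
* **Polarization** — ancestral/derived assignment requiring two
  concordant homozygous outgroups, with reclassification of called
  types into mutation types (a "deletion" whose deleted allele is
  ancestral is an insertion in the reference lineage).
* **Load and rescue** — unfolded site frequency spectra with a
  chi-square goodness-of-fit comparison of deleterious vs neutral
  spectra; per-individual masked load (fraction of deleterious loci
  heterozygous, `n_het / n_called`) and realized load (fraction
  homozygous derived); group trajectories across generation classes
  F1–F6 and immigrant-descendant classes L1–L3; Wilcoxon rank-sum
  group comparisons (exact where feasible); and counts of loci fixed
  for the derived allele that regained the ancestral allele after
  immigration.

A ground-truthed synthetic cohort generator (`simulateCohort()`) —
gene dropping from a three-founder bottleneck through full-sib lines,
a late two-immigrant rescue event, outgroups, and injected low-quality
artifact loci — makes the whole chain testable without sequencing
data.  See the methods vignette (`vignettes/methods.Rmd`) for the
models and design choices.

## Worked example

Simulate the default study conditions, filter, validate and compute
load trajectories:

```r
library(svload)

sim <- simulateCohort(simulationConfig(seed = 1))
res <- filterCascade(sim$cohort, decisions = truthDecisions(sim))
res$report
#>                      stage  DEL DUP INV Total
#> 1                      raw 1757 230 213  2200
#> 2            after_quality 1592 221 205  2018
#> 3 after_genotype_frequency 1389 186 180  1755
#> 4           after_curation 1389 177 171  1737

co <- res$cohort
mean(trioConcordance(co, sim$trios)$concordance)
#> [1] 0.9661839

pol <- polarize(co, sim$outgroups[, variantIds(co), drop = FALSE])
ov  <- classifyGeneOverlap(co, sim$geneModels)
grp <- loadByGroup(individualLoad(co, pol, ov), sim$sample_info)
grp[, c("group", "n", "mean_masked", "mean_realized")]
#>           group  n mean_masked mean_realized
#> 1            F1 21       0.294        0.0603
#> 2            F2 21       0.228        0.0962
#> 3            F3 21       0.185        0.1135
#> 4            F4 21       0.147        0.1381
#> 5            F5 21       0.139        0.1374
#> 6            F6 21       0.108        0.1573
#> 7            L1 14       0.319        0.0528
#> ...
```

Reading the output: the cascade removes the injected artifact loci
(raw 2200 → 1737); trio concordance near 96% reflects the 2%
genotyping-error rate; and across six generations of inbreeding
(F1 → F6) the masked load falls (0.294 → 0.108) while the realized
load rises (0.060 → 0.157) — inbreeding converts hidden heterozygous
load into expressed homozygous load.  The immigrant offspring (L1,
contemporaries of F6) show the rescue signature: the highest masked
load (0.319) and the lowest realized load (0.053) in the pedigree.

The same chain runs end to end, from files on disk through stamped
TSV outputs, with `runPipeline()` (or the thin CLI wrapper in
`inst/scripts/svload.R`):

```r
runPipeline(list(out_dir = "run1", seed = 1))
```

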