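---
title: "Structural-variant genetic load in small populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-variant genetic load in small populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svload)
```

## The problem

Small, isolated populations lose genetic diversity by drift and
accumulate deleterious alleles; inbreeding then exposes recessive
variants in homozygous form.  Structural variants (SVs) — deletions,
duplications and inversions — are an abundant and largely understudied
class of potentially deleterious mutations in conservation genomics.
`svload` implements the population-genetic analysis chain for SV
genotypes called from short-read data in a pedigree-structured
population with a known founding event and later immigration:

1. **Filtering** of raw SV calls by depth and genotype-quality
   thresholds, by genotype frequency, and by externalized curation
   decisions.
2. **Validation** by Mendelian concordance in parent–offspring trios
   and by PCA-based diagnostics of population structure and sequencing
   batch effects.
3. **Annotation** of gene overlap, repeat composition and length
   spectra.
4. **Polarization** of alleles into ancestral and derived states with
   two outgroup genomes, including reclassification of called SV types
   into mutation types.
5. **Load accounting**: unfolded site frequency spectra, per-individual
   masked and realized load, group comparisons across generation
   classes, and fixation/genetic-rescue bookkeeping.

Because real cohorts of this kind are rare and large, the package
includes a first-class synthetic cohort generator
(`simulateCohort()`) with complete ground truth, so every stage is
testable end to end without sequencing data.

## Data model

The central container is `SVCohort`, a `RangedSummarizedExperiment`
whose `"GT"` assay stores diploid genotypes as ALT-allele dosage
(0/1/2, `NA` missing), with one SV locus per row (1-based inclusive
coordinates, VCF convention) and one individual per column.  Per-locus
metadata carries the SV type, length, the duphold-style depth
fold-change relative to flanking sequence (DHFFC), the mean
genotype-quality score (MSHQ), and autosomal/biallelic flags.  BED
input is converted exactly from 0-based half-open to 1-based inclusive
at the boundary (via `rtracklayer`); VCF parsing goes through
`VariantAnnotation`.

SV length prefers `abs(SVLEN)` when the caller reports it and falls
back to `END − POS + 1`; callers disagree on these fields, so the rule
is explicit.  DHFFC and MSHQ are accepted either as per-record `INFO`
keys or as per-sample `FORMAT` fields reduced by the mean — smoove
output dialects vary, and the filters operate per record.

## The filter cascade

Quality thresholds follow the duphold/smoove recommendations with the
strictness exactly as conventionally printed: deletions pass when
`DHFFC < 0.7` (strict), duplications when `DHFFC > 1.3` (strict), and
every variant needs `MSHQ ≥ 3` (inclusive).  Inversions are
copy-neutral, so no depth expectation applies and a missing DHFFC on an
inversion is permitted.  Non-autosomal and multi-allelic records are
removed up front.

The genotype-frequency filter keeps loci with at least
`min_per_genotype` (default 2) individuals of *each* of the three
genotypes.  Missing genotypes are excluded from these counts — the
convention is consistent with how trios with missing calls are dropped
from concordance testing.  This filter deliberately sacrifices rare
variants for curatability; analyses that need rare alleles (the site
frequency spectrum) therefore run on the pre-genotype-frequency set.

Curation is externalized as a decision file (`variant_id` →
`ACCEPT`/`REJECT`), so the results of an image-review round (samplot /
plotcritic style) plug in directly; loci without a decision are
rejected by default (conservative), with `accept` and `error` policies
available.  Stages always run in the order quality → genotype
frequency → curation, and counts are reported per SV type at each
stage, so stage counts are non-increasing by construction and each
filter is idempotent on its own output.

## Validation

A child genotype is Mendelian-consistent when it can be assembled from
one allele per parent; in dosage coding the attainable child dosages
form the contiguous range `[(f==2)+(m==2), (f≥1)+(m≥1)]`.  Of the 27
ordered genotype triples, 15 are consistent.  Concordance is the
fraction of consistent loci among loci where all three members are
called.

PCA uses ALT-dosage coding (polarization is irrelevant for structure),
locus-mean centering and locus-mean imputation of missing genotypes —
the behaviour of standard SNP tooling.  No LD pruning is applied.  The
package also provides a silhouette-style two-group separation score
(`groupSeparation()`) used to diagnose sequencing-batch artifacts:
samples processed together share false calls, so a PCA of *rejected*
loci separates the batch while a PCA of accepted loci does not.

## Annotation and polarization

Each variant receives exactly one gene-overlap category, by priority:
`ENCLOSING` (the variant contains a full gene span, ends inclusive),
`PARTIAL_CDS` (it touches at least one coding base), `NONCODING`
(inside a gene but no CDS; introns and UTRs are not distinguished), or
`INTERGENIC` (added so the categories partition all loci).  For load
analyses, `ENCLOSING ∪ PARTIAL_CDS` is the putatively deleterious
class — an SV in coding sequence is very likely to disrupt the reading
frame or remove the product entirely — and intron-confined variants are
the putatively neutral comparison.

Repeat composition attributes every base of a variant to at most one
repeat class; where annotations overlap, the feature with the smaller
start wins, ties broken by class name.  The rule is deterministic and
conserves variant length exactly (property-tested on random layouts).
Length spectra use half-open bins; `peakComposition()` aggregates the
repeat content of a closed length window, such as the ~190 bp deletion
peak produced by SINE presence/absence polymorphism.

Polarization requires both outgroups homozygous for the same allele;
heterozygosity, disagreement or missingness in either outgroup leaves
the locus unpolarized (the strict both-required reading).  Because
calls are made against a reference assembly, a "deletion" whose deleted
allele is ancestral is actually an insertion in the reference lineage;
the mutation-class table in `?polarize` makes this reclassification
explicit.  Downstream load analyses are restricted to loci where the
reference carries the ancestral allele, so hom-ALT means
homozygous-derived and gene annotation (built on the reference) is not
confounded by derived sequence present in the reference itself.

## Load statistics

**Derived allele frequency** uses 2 × (non-missing individuals) as the
denominator, keeping loci with different missingness comparable.  The
**unfolded SFS** bins polymorphic frequencies into 0.05-wide intervals
`[0,0.05), …, [0.95,1]`.

The **goodness-of-fit test** compares the deleterious spectrum with
expected counts formed from the neutral spectrum's bin proportions,
pooling bins from the right until every expected count is ≥ 5 (standard
Pearson practice), with `Σ(obs−exp)²/exp` on `bins − 1` degrees of
freedom.  Treating the neutral proportions as known is justified in the
intended regime, where intronic loci outnumber coding ones by roughly
two orders of magnitude; the calibration test draws both spectra from
one distribution at a 90:1 size ratio and verifies a type-I error near
the nominal 5%.  At comparable class sizes the test would be
anti-conservative — it is not designed for that use.

**Masked load** is the fraction of an individual's called deleterious
loci in heterozygous state; **realized load** the fraction homozygous
derived.  The three genotype fractions partition the called loci, an
identity asserted per run.  Group summaries order generation classes
F1–F6 (descendants of the founders, by generations to the closest
founder) then L1–L3 (descendants of later immigrants).

**Group comparisons** use the unpaired two-sided Wilcoxon rank-sum
test: the exact Mann–Whitney null distribution when there are no ties,
full enumeration of assignments for tied samples up to 20 total
observations, and the tie-corrected normal approximation beyond (full
enumeration at n = 25 would need ~5 million assignments; the exact
distribution is identical whenever ties are absent, so the
approximation is only ever used for large tied samples).  All-tied
input returns p = 1.

**Fixation/rescue accounting** counts loci fixed for the derived allele
in a pre-immigration subset (every called genotype homozygous derived,
with a minimum of 5 called individuals to avoid spurious fixation from
missingness) and how many regained the ancestral allele after
immigration.  The founder-fixation rule (no heterozygote and no
homozygous-ancestral call anywhere in the original population) has no
minimum-call requirement but is sensitive to genotyping error: a single
miscall among ~130 individuals disqualifies a locus, so this quantity
is only informative on error-free (curated or simulated noise-free)
genotypes.

## The synthetic cohort generator

`simulateCohort()` emulates the study conditions the analysis chain is
built for: a source population in Hardy–Weinberg equilibrium, a
three-founder bottleneck followed by six generations of closed-line
inbreeding (21 individuals per generation class), a late immigration
event in which two reproducing immigrants sire 14 L1 offspring
(mirroring a 14-vs-21 rescue comparison), 40 source-population samples,
two outgroup individuals, and seven validation trios.  Deleterious loci
are placed so they overlap coding sequence (enclosing a small gene when
the variant is long enough), neutral loci fall deep inside introns, and
the deletion/duplication length peaks are coupled to SINE/LINE repeat
annotations.

Key generative choices:

* **Founder frequency laws.** Derived-allele frequencies come from a
  two-parameter Beta family: `Beta(1.5, 8.5)` (mean 0.15) for the
  deleterious class and `Beta(1.5, 4.5)` (mean 0.25) for the neutral
  class.  Only the qualitative left shift of the deleterious spectrum
  is empirically established; the specific parameters were chosen once
  so that the shift is detectable at desk-scale locus counts
  (400 deleterious / 1600 neutral by default).
* **No selection during transmission.** The deleterious/neutral
  difference is encoded in founder frequencies only; load dynamics then
  arise from drift and inbreeding alone, which gene dropping
  reproduces.
* **Mating scheme.** The default is full-sib line mating: each of three
  lines continues through a brother–sister pair, giving a deterministic
  inbreeding coefficient per generation (F ≈ 0, 0.25, 0.375, 0.50,
  0.59, 0.67).  A design-stage power analysis showed that uniformly
  random pairing makes the mean kinship path itself a random walk, so
  monotone load trajectories across F1–F6 appear in only a minority of
  runs even with many loci — the signal the generator exists to produce
  would drown in pairing noise.  Random pairing remains available via
  `mating = "random"` for studying exactly that variability.
* **Noise model.** Genotyping errors (2% default) are uniform miscalls
  to one of the two other genotypes; missingness (2%) is uniform.
  Under a 2% error rate a trio locus has ≥ 1 miscall with probability
  ≈ 6%, roughly half of which produce Mendelian inconsistencies —
  hence trio concordance near 96%, bracketing what curated short-read
  SV data achieve.
* **Artifacts.** Injected false loci (10% by default, 30% in the
  artifact-removal tests) carry out-of-threshold quality values —
  injected deletions always show no depth drop (DHFFC ≥ 0.7); some
  duplication/inversion artifacts pass all thresholds and are caught
  only by curation — and heterozygote-enriched genotypes confined to a
  designated "sequencing batch" (40% of samples), reproducing the
  batch-clustering signature of false calls.
* **Outgroups.** 60% of loci have both outgroups homozygous ancestral;
  the rest are discordant, heterozygous or missing in one outgroup, so
  roughly 60% of loci polarize.

What the generator does **not** emulate: sequence-level reads and
breakpoints, recombination (loci are unlinked), realistic chromosome
lengths (each locus sits in its own 50 kb slot), selection, and
non-uniform error processes (e.g. coverage-dependent genotyping error).
Passing tests therefore demonstrate that the statistics recover known
truth under the stated generative model — not that any particular real
dataset is error-free.

## Numerical and degenerate-input choices

* Frequency bins are `[lo, hi)` with the last bin closed at 1;
  monomorphic loci are excluded from spectra.
* An undefined ratio (no called loci for an individual, no testable
  loci for a trio) is reported as `NA`, never silently dropped.
* A PCA on an all-constant matrix and a goodness-of-fit with fewer than
  two pooled bins are errors, not warnings.
* Repeat-attribution tie-breaks (smaller start, then class name) and
  the curation default (reject undecided loci) are deterministic and
  documented rather than order-dependent.
* All simulation randomness flows from a single integer seed; the same
  configuration and seed reproduce byte-identical VCF output.

## Problem sizes

Default study conditions are 2000 true loci (plus injected artifacts)
across 189 samples; the test suite runs the full chain on these sizes
across ten seeds for the drift/rescue properties, and uses scaled-down
cohorts (300–500 loci) for unit-level checks.  These sizes were chosen
so the qualitative signals (monotone load trajectories, rescue
direction, spectrum shift) are statistically stable across seeds while
a complete run of the suite stays interactive.

## Known limitations

* The goodness-of-fit comparison assumes a much larger neutral than
  deleterious class; it is anti-conservative at comparable sizes.
* Founder-fixation counts require error-free genotypes (see above).
* BND/translocation records and multi-allelic SVs are out of scope:
  the former are skipped on read, the latter flagged and removed by the
  quality filter.
* Deleteriousness is assigned by gene overlap, not by functional
  prediction; codon-level effect classes do not transfer to multi-codon
  variants.
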