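---
title: "Family-based variant prioritization with VariantFunnel"
author: "VariantFunnel maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant prioritization with VariantFunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantFunnel)
```

## The problem and the model

Whole-exome sequencing of a cancer-affected family typically yields on the
order of $10^4$ rare variants after basic frequency screening; at most a
handful are plausible germline predisposition candidates. VariantFunnel
implements the tiered prioritization model used in familial
colorectal-cancer studies: an ordered funnel of per-variant filters in
which the survivors of each stage are exactly the inputs of the next,

$$\text{QC} \rightarrow \text{frequency} \rightarrow \text{segregation}
\rightarrow \text{coding} \rightarrow \text{non-synonymous} \rightarrow
\text{CADD} \rightarrow \text{conservation} \rightarrow
\text{intolerance} \rightarrow \text{deleteriousness}.$$

Every filter is a pure predicate over one variant's annotations, so the
stage order affects only the per-stage survivor counts, never the final
candidate set. The placement of QC and frequency filtering ahead of
segregation is this package's fixed convention.

The segregation model is deliberately minimal. Each family member carries
a *role* derived from phenotype: cancer cases are **obligate carriers**
(under a dominant predisposition model they are expected to carry the
causal allele), polyp patients are **optional carriers** (colorectal
polyps may express a preliminary disease stage, so their carriage is
uninformative in both directions), and unaffected members below the
family's earliest onset age are **uninformative**. A variant segregates
exactly when every obligate carrier has a carrying genotype
(heterozygous or homozygous alternate by default). There is no
inheritance-mode likelihood, no founder check, no de novo model, and no
requirement of *non*-carriage in any member: published candidate tables
from such analyses contain variants carried by unaffected relatives, so
the filter imposes none. Role overrides are stored explicitly on the
pedigree, keeping deviations auditable.

## Thresholds and their boundary semantics

The defaults of `filterConfig()` reproduce the standard tier rules, and
the boundary inclusivity follows how each rule is conventionally stated
rather than normalizing everything to one convention:

| stage | rule | boundary |
|---|---|---|
| QC | quality > 20, coverage > 5x | strict |
| frequency | population MAF <= 0.001; local cohort < 0.05 | inclusive / strict |
| CADD | PHRED-scaled CADD >= 10 (top 10% of substitutions) | inclusive |
| conservation | >= 2 of {GERP++ >= 2.0, PhastCons > 0.3, PhyloP >= 3.0} | mixed, per score |
| intolerance | favorable fraction >= 60% of {3 intolerance scores < 0, Z > 0, pLI >= 0.9} | inclusive |
| deleteriousness | favorable fraction >= 60% of the 12-member panel | inclusive |

The two 60% thresholds are inclusive because a candidate sitting exactly
at 3/5 = 60% on the intolerance panel is a legitimate survivor in the
worked example this package ships; an exclusive reading would silently
change the published outcome.

Missing data are handled by explicit, configurable policies:

* **Frequencies** (`missing_frequency_policy`, default `treat_as_rare`):
  a variant absent from a reference population is at least as rare as
  any cap, so missing frequency fields pass; `drop` inverts this for
  conservative use.
* **Conservation**: a missing score counts as *unsatisfied*, never as a
  smaller denominator — the rule is "2 of 3", a fixed denominator.
* **Panel fractions** (`missing_score_policy`, default
  `exclude_from_denominator`): favorable percentages are computed over
  non-missing panel members, which is how published percentages such as
  83.33 (5/6) arise for variants annotated by only part of the panel;
  `count_unfavorable` fixes the denominators at 12 and 5. Under either
  policy an entirely missing panel **fails closed**, because screened
  candidates were by construction annotatable.

The deleteriousness panel comprises ten individual predictors (SIFT,
PolyPhen-2 HumDiv/HumVar, LRT, MutationTaster, MutationAssessor, FATHMM,
VEST3, PROVEAN) and two meta-predictors (MetaSVM, MetaLR), with the
meta-predictors' reliability index as the twelfth member. Favorable
categorical codes are fixed by `defaultFavorabilityMap()`; unrecognized
codes are unfavorable (never an error), and the two numeric members use
inclusive thresholds (VEST3 >= 0.5, reliability index >= 5).

By default the intolerance panel pools all five available members for
every variant. Gene constraint metrics are arguably type-specific — the
missense Z-score describes missense depletion, pLI loss-of-function
depletion — so `intoleranceFilter(..., type_specific = TRUE)` scores Z
only for missense and pLI only for LoF variants. It is not the default
because published panel percentages (60/80/100) are consistent with the
pooled five-member denominator.

## The synthetic data generator

Real family WES data cannot ship with a package, so `generateDataset()`
emulates the statistical structure the funnel assumes:

* **Genotypes** are produced by Mendelian gene dropping through the
  six-member family template (`crcFamilyPedigree()`): founders draw two
  alleles binomially from a per-variant founder frequency; offspring
  inherit one allele from each parent uniformly; a parent absent from
  the pedigree (an unsequenced spouse) contributes a population-drawn
  allele. Background genotypes are generated under the null of no
  linkage to disease, so the segregation-stage survival of background
  variants estimates the filter's false-pass rate — it is reported, not
  asserted against any published count, because real per-stage counts
  depend on relatedness structure, linkage disequilibrium and calling
  noise that the generator does not model.
* **Founder frequencies** are log-uniform on $[5\times10^{-5},
  2\times10^{-3}]$, emulating a pool that has largely passed population
  frequency screening while keeping a tail above the 0.1% cap so the
  frequency stage does real work.
* **Annotation scores** come from a two-regime mixture
  (`defaultScoreRegimes()`): the deleterious-like regime centers every
  score on the passing side of the default thresholds, the benign-like
  regime below them, and both place mass on both sides of every
  threshold. Regimes are parameterized distributions, not resampled real
  annotations, keeping the package download-free. Deleteriousness
  predictor calls are emitted only for non-synonymous SNVs, mirroring
  dbNSFP's coverage; conservation and gene-level panels are missing for
  a small fraction of rows.
* **Planted variants** carry exactly their specified carrier sets and
  annotations; `plantedVariant()`'s defaults pass every default
  threshold, so a plant whose carriers cover the obligate set is
  recoverable by construction — the recovery property the test suite
  asserts over 100 seeds.

What passing synthetic tests does *not* show: robustness to annotation
pipelines with different column dialects, to correlated predictor errors
(real dbNSFP calls are strongly correlated; the generator draws them
independently given the regime), or to the segregation survival rates of
really related genomes.

## Numerical and engineering choices

* Positions are 1-based throughout, matching `chrom_pos_ref_alt`
  identifiers; no half-open intervals are needed.
* Genotype tokens accepted on input: `0/0`, `0/1`, `1/0`, `1/1`, `./.`
  and the word synonyms `ref`/`het`/`hom`/`missing`; unphased only.
* Candidate ranking is CADD descending with chromosome/position
  tie-break — an artifact convention for stable output; the final
  *choice* among candidates (external database lookups, literature) is a
  judgment call outside algorithmic scope, and such annotations ride
  along as passthrough columns.
* The exact carrier test is the standard two-sided convention:
  conditional on both margins, sum hypergeometric point probabilities at
  most the observed one (computed via `stats::fisher.test`; the test
  suite checks it against an independent exhaustive enumeration). The
  odds ratio is the sample cross-product ratio, flagged `unbounded` on a
  zero denominator cell rather than reported as a number.
* Degenerate inputs fail loudly and early: tables reject malformed rows
  with line numbers, pedigrees reject dangling parents and duplicate
  identifiers, cyclic parentage is detected before gene dropping, funnel
  reports with non-monotone counts are refused at construction.

## Problem sizes in the test suite

The suite exercises the logic at sizes chosen to make the properties
exhaustive where exhaustion is feasible: all $2^{12}$ deleteriousness
panels and $3^5$ intolerance panels against a brute-force counting
oracle, all $4^6$ genotype assignments of the six-member family against
a brute-force segregation oracle, all 2x2 carrier tables with group
totals up to 12 (8,100 tables) against the enumeration oracle, and 100
seeded synthetic datasets of 5,000 background variants each for
planted-variant recovery. End-to-end examples use the packaged
six-variant fixture, which the default configuration passes in full.

## Known limitations

* The funnel consumes already-annotated variant tables; it performs no
  alignment, calling, or annotation, and never queries external
  databases.
* Scores are consumed, never derived: the package does not recompute
  CADD, conservation or constraint metrics from sequence.
* Single-family analysis only; no multi-family joint modeling, kinship
  verification, or penetrance estimation.
* The alignment audit expects pre-aligned input and treats any gap as a
  mismatch, including a reference gap.
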