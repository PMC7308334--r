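---
title: "Detecting and testing deletion–SNV compound heterozygosity in family cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and testing deletion–SNV compound heterozygosity in family cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comphet)
```

## The question and the model

An inherited genomic deletion removes one copy of every gene it spans. If
the remaining allele of such a gene also carries a functional sequence
variant, the two hits together — a "double hit" form of compound
heterozygosity — can produce a phenotype that neither hit alone would. In a
family study design, the natural comparison group for the affected child
(the proband) is the parent who transmitted the deletion: both individuals
carry exactly the same hemizygous region, so the sequence queried in each
is identical in gene identity and length by construction.

`comphet` implements this analysis end to end for cohorts of proband–parent
pairs and complete trios:

1. **CNV filtering and family prioritization.** Deletion/duplication calls
   are retained when concordant across ≥2 calling algorithms, below 10%
   cohort frequency, and longer than 5 kb. Multiplex families (more than
   one affected child) and probands carrying a homozygous deletion are
   excluded. Remaining families are ranked by a weighted rank-sum score
   that doubles the deletion terms relative to the duplication terms:
   `R = 2*(rank of inherited deletion count + rank of brain-relevant
   inherited deletion count + rank of inherited deletion fraction) +
   1*(the three duplication analogues)`.
2. **Event detection.** For each inherited deletion, the genes it affects
   are determined with a 500 kb fuzzy border at both ends. Every
   QC-passing variant of the proband and of the transmitting parent inside
   those genes becomes a candidate event; it is *scenario 1* when its
   position falls within the reported deletion boundaries (the variant sits
   on the remaining allele of a hemizygous region and presents as a
   homozygous call) and *scenario 2* when it falls in the gene but outside
   the deletion. Only scenario-1 events are counted.
3. **Statistics.** The pooled proband and pooled parent sequences are
   identical, so under the null hypothesis the pooled variant counts split
   50:50. The count test is the 1-df chi-square goodness of fit against
   that split. Predicted deleteriousness is tested by summing scaled CADD
   scores per individual and fitting a logistic regression of group on the
   sum. With three analyses, p-values are compared against a Bonferroni
   threshold of 0.05/3.
4. **Deleteriousness filters.** A CADD-10 filter (scaled score ≥ 10, i.e.
   the top 10% of possible genome variants) and a protein-altering filter
   (missense, missense + splice-region, splice-region + intron categories)
   are combined as a union; sensitivity re-analyses drop synonymous
   variants or variants in segmental duplication regions and re-run the
   count test.

## Variant quality control and genotype rules

A variant call passes QC when **all** of the following hold: depth ≥ 10
reads; Phred quality > 20; non-reference allele fraction > 15%; more than 3
supporting reads on **each** strand; and at most 5 identical supporting
reads (a guard against PCR/optical co-linearity). A metric recorded as
absent fails its criterion — absence is never treated as zero passing. The
strand-support threshold is read strictly (`> 3`); it is configurable via
`qc_thresholds()` for pipelines that intend `>= 3`.

Inside a deletion the locus is hemizygous and genotype callers report the
single remaining allele as a homozygous call; `comphet` accepts both the
haploid (`1`) and diploid (`1/1`) encodings and normalizes them to one
`hom_alt` state. Two coding rules then apply at each site:

* homozygous-reference and uncalled genotypes are both coded *missing* and
  can never yield an event for that carrier;
* when proband and transmitting parent both show the identical
  hemizygous/hom-alt allele, the variant was inherited along with the
  deletion and both calls are excluded. Het-vs-hom differences are
  retained; multi-allelic sites are decomposed per alternate allele before
  this comparison, because the rule compares alleles, not sites.

## Numerical and design choices

* **Coordinates.** Everything internal is 0-based half-open (BED
  convention). VCF positions and `start–end` style CNV tables are treated
  as 1-based inclusive at the boundary and converted on ingestion; the
  conversion is an involution, tested as such.
* **Fuzzy border scope.** The 500 kb border applies only when deciding
  which genes a deletion affects. Scenario-1 membership uses the reported
  deletion boundaries without the border: the event definition is "within
  the boundaries of the deletion region", whereas the border compensates
  for imprecise CNV breakpoint reporting when assigning gene content.
* **No continuity correction.** The count test uses the plain 1-df
  goodness-of-fit statistic. A Yates-corrected version of the test gives
  materially different values at these sample sizes (6.20 instead of 6.69
  at a 68/41 split) and is deliberately not offered; the implementation is
  validated against four published statistic/p-value pairs in the test
  suite.
* **Rank ties.** All priority-score ranks use average (midrank)
  assignment — deterministic and standard. The preference for few de novo
  CNVs is a separate ascending sort key applied before the score, since
  the score formula itself contains no de novo term. The subscripts of the
  published score formula admit more than one reading; the feature set
  chosen here (counts, brain-relevant counts, inherited fractions) follows
  the accompanying prose, and `priority_score()` accepts any feature table
  so alternative readings can be swapped in.
* **Separation in the burden test.** Under complete or quasi-complete
  separation the logistic fit is flagged `converged = FALSE` and no
  estimate is reported, rather than returning a numerically divergent
  coefficient.
* **CADD-10 boundary.** The scaled score is a genome-wide rank, so
  "top 10%" is implemented as scaled ≥ 10, inclusive at the boundary;
  the threshold is a parameter.
* **Missing CADD scores** abort aggregation by default (`"error"` policy);
  a `"drop"` policy is available for exploratory runs. A score lookup that
  misses returns `NA`, never 0.
* **Parent denominators.** The percentage of parent carriers depends on
  whether all sequenced parents or only transmitting parents are counted;
  `carrier_summary()` therefore takes the denominator as an argument
  rather than hard-coding either convention.

## The synthetic cohort generator

Real data for this design live in controlled-access repositories, so the
package ships a generator (`generate_cohort()`) whose defaults are the
study conditions the pipeline was built for: 149 families of which 47 are
complete trios; one inherited heterozygous deletion per family; an average
of 3.08 brain-relevant genes per deletion; consequence categories at the
observed pooled distribution over nine classes; and scaled CADD scores
drawn Exponential(ln(10)/10), which makes P(score ≥ 10) = 0.10 exactly, so
the CADD-10 filter's selectivity is analytically known. The parental
per-gene variant rate defaults to 0.09 — sized so a default cohort carries
on the order of 41 parental and, at the default rate ratio 68/41, about
68 proband variants — and the proband enrichment is plantable through
`proband_rate_ratio` (1 = null).

Genes-per-deletion is generated as 1 + Poisson(2.08): every analyzed family
must have at least one brain-relevant deleted gene, and the shift preserves
the 3.08 mean exactly. This, like the uniform placement of variants over
the gene body, is an assumption, not an observed distribution. A
configurable fraction of genes (default 0.2) straddles a deletion boundary
so that scenario-2 variants arise; both trio parents receive genotype data
but only the transmitting parent carries the deletion, which exercises the
pairing logic; hemizygous variants are emitted in the homozygous encoding
with the non-carrier of the pair homozygous-reference at the site, which
exercises the missing-coding rule.

What the generator does **not** emulate: read-level artifacts, genotyping
error beyond threshold-crossing QC metrics, linkage between variants,
overlapping or nested CNVs, multi-deletion families (one deletion per
family by default), or population structure. A perfect detection score on
synthetic cohorts therefore validates the bookkeeping — interval logic,
genotype rules, pairing — not robustness to noisy real-world calls.

Every cohort carries a truth record of planted events. The package's test
suite uses it to require exact recovery: on a default-sized cohort the
pipeline must detect 100% of planted scenario-1 events with zero false
positives when QC metrics are generated above thresholds.

## Problem sizes in the test suite

Deterministic unit tests run on handcrafted families and 30-family
cohorts. The statistical properties use: 200 replicates per rate-ratio
point for the power-monotonicity check; 2000 null binomial splits of a
109-variant total for the type-I error of the count test (the discrete
null rejection rate at that total is about 5.5%, inside the 5% ± 2 point
band asserted); 100 replicates of n = 400 for the burden-test coverage
property (planted coefficient recovered within 2 standard errors in at
least 93% of fits); and 100,000 draws for the CADD-10 selectivity check.
These sizes were chosen so each property is measured with a Monte-Carlo
error comfortably below the asserted band.

## Known limitations

* The real-data burden-test coefficients cannot be reproduced without
  per-individual CADD sums, which are not published; the logistic burden
  test is validated by its coverage and null-behaviour properties instead.
* The intersection of the two deleteriousness filters (rather than their
  union) is not offered as a headline analysis — at realistic event counts
  it is underpowered — though both flags are reported per variant.
* De novo vs inherited origin of SNVs is consumed from input annotations
  when present, never inferred from raw trio genotypes.
* Covariates (site, sex) are not included in the burden regression by
  default; the model formula is a natural extension point.
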