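Package: comphet
Title: Compound Heterozygosity of Inherited Deletions and Sequence Variants in Family Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and burden analysis of compound heterozygous events in
    which an inherited genomic deletion co-occurs with a single nucleotide
    variant on the remaining allele. Provides readers for pedigree, CNV, VCF,
    gene and CADD score tables; CNV call filtering and rank-based family
    prioritization; gene-content determination with a fuzzy border; variant
    quality control and hemizygous genotype handling; scenario classification
    of deletion-overlapping variants; pooled-count chi-square and logistic
    CADD burden tests with Bonferroni correction; CADD-10 and
    protein-altering deleteriousness filters with sensitivity re-analyses;
    and a reproducible synthetic family-cohort generator so the full
    pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    IRanges,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
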