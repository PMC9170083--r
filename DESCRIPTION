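Package: hlaase
Title: Allelic Expression Balance and cis-eQTL Analysis for HLA Class I
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the balance of expression between the two
    alleles an individual carries at the highly polymorphic HLA class I
    loci (HLA-A, -B, -C). Implements the allele-specific expression (ASE)
    statistic (lower-expressed allele over total), an allele-constrained
    permutation test of expression balance, locus and allele expression
    summaries with cytokine-stimulation fold changes, haplotype-level
    co-expression regressions, and a compact cis-eQTL stage with variant
    quality control, rank-based normalization, gene-level permutation
    significance with a beta approximation, genotype-by-stimulation
    interaction tests, Storey pi1 replication estimates and LD r-squared.
    A variance-components lognormal simulator generates synthetic cohorts
    (haplotypes, allelic expression tables, VCF genotypes with planted
    cis effects) so every stage can be exercised and calibrated without
    access to donor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
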