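Package: cdase
Title: Condition-Dependent Allele-Specific Expression from Allelic Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cis-regulatory genotype-by-environment interactions in
    expression data by analysing allele-specific expression (ASE) at
    heterozygous transcribed SNPs across treatment conditions. Implements
    read-coverage filtering of informative sites, SNP-wise static ASE
    (exact binomial tests combined across samples by Fisher's method with
    Benjamini-Hochberg FDR control), SNP-wise condition-dependent ASE
    (per-sample Fisher exact tests on 2x2 allelic count tables between a
    control and each treatment), gene-wise meta-analytic ASE with an
    empirical resampling null, haplotype-level allelic-ratio verification
    from phased SNP sets, and a beta-binomial simulator of allelic count
    data with known truth for calibration and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
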