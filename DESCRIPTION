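Package: taucor
Title: Conditional Gene-Based Association Analysis Correcting for the
    Regional Polygenic Background
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conditional gene-based association (GBA) analysis from GWAS
    summary statistics. Estimates a regional polygenicity parameter tau --
    the variance of random extragenic SNP effects, proportional to local
    SNP heritability -- by maximum likelihood from the z statistics of
    SNPs surrounding a gene, then corrects the intragenic LD matrix so
    that the distribution of intragenic z statistics becomes conditionally
    independent of the regional polygenic background. Includes gene-based
    tests operating on a z vector and a covariance matrix (Burden, SKAT,
    SKAT-O, PCA, and the ACAT Cauchy combination) with an exact
    chi-square-mixture p-value engine, a direct simulator of GWAS summary
    statistics over a gene and its surrounding region, and
    sensitivity/specificity/accuracy evaluation of gene-level calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
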