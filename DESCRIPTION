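Package: poolassoc
Title: Association Mapping with F2-Family Pool Allele Frequencies from
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for association studies in outcrossing crops where
    phenotypes are measured on F2 full-sib family pools and the "family
    genotype" is an allele frequency estimated from pooled sequencing
    (GBS) read counts. Provides closed-form population-genetic
    quantities for family pools (pool genotype distributions, genetic
    and binomial-noise variances, measurement-error attenuation), a
    regression estimator of the allele-substitution effect with
    attenuation correction for finite sequencing depth, a synthetic-data
    simulator (one- and two-locus, variable depth, per-read error,
    genotype calling), and a replicated Monte-Carlo power engine for
    design studies under a fixed sequencing budget.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
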