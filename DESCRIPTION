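Package: vwdprev
Title: Population-Based Prevalence Estimation for von Willebrand Disease
    from Aggregated Variant Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the population prevalence of von Willebrand disease
    (VWD) from gnomAD-style per-population allele summaries of VWF variants.
    Implements a conservative five-rule pathogenicity cascade (known disease
    database membership, truncating consequences, core splice-site
    disruption, 4-of-4 splice-predictor consensus, 7-of-7 missense-predictor
    consensus), per-population affected-allele aggregation with recurrent-
    variant rankings and a homozygote census, and Hardy-Weinberg prevalence
    models for dominant (2pq), recessive (q^2) and compound-recessive
    (q^2 + 2*q*q_null) inheritance, with configurable variant exclusions and
    minor-allele-frequency cutoffs. Ships a seeded synthetic-cohort
    generator with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
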