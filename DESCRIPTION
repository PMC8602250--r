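Package: audiogene
Title: Variant Interpretation and Audiometric Phenotyping for Mid-Frequency Hearing Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale diagnostic pipeline for mid-frequency (cookie-bite)
    sensorineural hearing loss cohorts. Decomposes and left-normalizes VCF
    variants against reference windows, attaches gene, consequence, population
    frequency and in-silico score annotations from a sidecar table, filters by
    popmax allele frequency and a virtual deafness gene panel with whole-exome
    fallback, classifies variants under strength-modified ACMG/AMP evidence
    combining (categorical rules authoritative, Bayesian points advisory),
    grades and shape-classifies pure-tone audiograms, resolves per-family
    diagnostic status from pedigrees and inheritance modes, and summarizes
    cohort yield. Ships a seeded synthetic cohort generator that plants a
    transcribed clinical variant fixture among decoy variants so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
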