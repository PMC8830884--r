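Package: trioDNM
Title: Germline De Novo Mutation Detection and Rate Estimation from Trio Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects germline de novo mutations (DNMs) as Mendelian violations in
    multi-sample trio/pedigree variant calls and estimates per-site per-generation
    mutation rates. Implements the full hard-filter taxonomy used by pedigree
    mutation-rate studies (site-level GATK-style annotation filters; per-sample
    depth, genotype-quality, allelic-depth, allelic-balance, strand and cluster
    filters; population/region exclusion), named filter presets for five published
    pipelines, false-discovery-rate corrections (PCR validation, transmission
    deviation), callable-genome estimation (count-based and probabilistic),
    false-negative-rate estimation (spike-in, allelic-balance tail, site-filter
    proportion), Wilson confidence intervals for the rate, binomial study-design
    calculators, a synthetic trio simulator with a ground-truth ledger, and
    concordance/spectrum/transmission reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: VariantDetection, Genetics, Sequencing, Software
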