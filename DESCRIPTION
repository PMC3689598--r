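Package: methylsieve
Title: Methyl-Sensitive Restriction Profiling: Simulation and Site Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for restriction-based profiling of 5-methylcytosine (5mC)
    and 5-hydroxymethylcytosine (5hmC). Provides an in-silico,
    mark-aware restriction digestion kernel with a registry of
    isoschizomer pairs (MspI/HpaII, FspBI/BfaI) and frequent cutters
    (TasI), idealized simulators of three enrichment chemistries
    (methylation-sensitive representational difference analysis,
    its hydroxymethylation variant, and a HELP-style methyl-sensitive
    cocktail assay), a synthetic genome and methylome generator with
    ground-truth provenance, a read-to-site calling pipeline (adaptor
    trimming, greedy identity clustering, seeded alignment with
    unique-placement filtering, extension to the nearest restriction
    site), genomic-feature annotation of called sites, and a
    digestion-resistance q-PCR estimator with an exact rank-sum test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
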