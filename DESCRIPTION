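Package: greenbeardr
Title: Detection of Polychromatic Greenbeard Loci from Segregation and
    Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for detecting a polychromatic greenbeard
    locus in social amoebae. Computes normalized segregation values (nsv) from
    per-fruiting-body genotype compositions, fits a gamma null distribution to
    self-mix controls, runs a genome-wide scan correlating per-gene protein
    distances with pairwise segregation under a Sidak familywise threshold,
    classifies diversifying sites by per-column Shannon entropy, measures
    tree and distance-matrix concordance (neighbor joining, patristic and
    cophenetic distances, Robinson-Foulds), links protein-binding and
    slug-migration phenotypes to segregation, and generates seeded synthetic
    datasets with a planted greenbeard locus for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    MASS,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
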