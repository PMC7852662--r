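Package: mitodemog
Title: Demographic Inference from Mitogenome Haplotype Alignments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Population-genetic demographic inference for mitochondrial
    genome alignments: per-haplogroup diversity statistics (haplotype
    number and diversity, segregating sites, nucleotide diversity, mean
    pairwise differences), Tajima's D and Fu's Fs neutrality tests with
    coalescent-null significance, mismatch-distribution fitting under the
    sudden-expansion model with parametric-bootstrap goodness-of-fit and
    raggedness tests, conversion of mutational time to calendar years under
    a tiered time-dependent substitution-rate ledger, median-joining
    haplotype networks with star-likeness diagnostics, and a coalescent
    simulator for constant-size and two-epoch expansion demographies that
    backs both the test suite and the parametric bootstrap.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
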