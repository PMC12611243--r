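Package: quasipop
Title: Intra-Host Viral Quasispecies Diversity and Transmission Bottlenecks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of intra-host populations of amplicon-sequenced RNA
    viruses, built around the mycovirus Cryphonectria hypovirus 1 (CHV1).
    Collapses count-annotated amplicon haplotypes into viral variants,
    computes Nei's gene diversity and codon-aware nucleotide diversity
    (pi, piN, piS by the Nei-Gojobori pathway method), calls intra-host
    mutations against a reference with SnpEff-style effect categories,
    quantifies shared variants and transmission bottlenecks between
    paired populations (vertical conidial and vic-locus-gated horizontal
    transmission), and provides a seeded quasispecies simulator with
    founder-sampling transmission so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
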