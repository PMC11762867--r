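Package: nanomock
Title: Simulation of Nanopore-Style Mock Metagenome Samples with Exact
    Read Abundances
Version: 0.1.0
Authors@R:
    person("Daniel", "Reyes", email = "dreyes@example.org", role = c("aut", "cre"))
Description: De novo simulator of long-read (Nanopore-style) metagenomic
    sequencing samples with exactly controlled per-organism read
    abundances. Supports absolute, relative and pseudo-random abundance
    modes, taxa-with-subtaxa designs, host-microbiome scenarios and
    serial-dilution batches with replicates; a truncated-Gaussian read
    length model; and an error-insertion algorithm with
    transition/transversion-weighted substitutions, geometric insertions
    and single-base deletions. Samples are emitted as FASTA together
    with abundance, error-profile, error-distribution and run-parameter
    reports plus a per-read truth table, for validating taxonomic
    classifiers and diagnostic assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
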