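Package: xcikit
Title: Desk-Scale Pipelines for X-Chromosome Inactivation Sequencing Assays
Version: 1.0.0
Authors@R:
    person("xcikit", "maintainers", email = "xcikit@example.org",
           role = c("aut", "cre"))
Description: Reusable implementations of five computational procedures used
    to study X chromosome inactivation (XCI): candidate selection from
    affinity-purification mass-spectrometry rank gains ("FLAG-out"),
    allele-specific expression scoring of padlock-captured SNP counts
    (allelotyping), chromatin-compaction scoring from ATAC-seq transposon
    insertion sites binned at 1 Mb, one-control SHAPE-MaP chemical-probing
    reactivity profiling with PCA of replicate profiles, and first-order
    exponential decay fitting of transcript abundance after transcription
    blockade.  A synthetic-data module generates ground-truth-labelled
    inputs for every stage so each pipeline can be verified at desk scale
    without any sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
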