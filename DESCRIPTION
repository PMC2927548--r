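Package: xenopass
Title: Cross-Species Classification of Cancer Driver and Passenger Gene Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing cancer driver from passenger gene
    alterations by comparing tumor cohorts across species whose genomes
    differ in local gene arrangement. Includes synteny-block and
    rearrangement-breakpoint detection from ortholog gene order,
    quality-aware variant calling from paired tumor/normal Sanger-style
    exon reads, codon-level effect annotation (nonsense, frameshift),
    delta-Ct qPCR alteration testing, array-CGH segmentation with
    altered-genome-fraction estimation, and a rule-based classifier that
    fuses per-species alteration evidence with synteny context into
    driver/passenger/unresolved calls. A simulation suite generates every
    input the pipeline consumes, including a two-genome scenario in which
    a gene pair is adjacent in one genome and megabases apart in the
    other, so that collateral (proximity-driven) mutagenesis can be told
    apart from recurrent driver disruption.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    IRanges,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
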