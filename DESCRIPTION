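Package: subsysfocus
Title: Subsystem Functional Profiling of Shotgun Metagenomes with
    Taxonomy-Driven Database Reduction
Version: 0.1.0
Authors@R:
    person("Metagenomics", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns shotgun metagenomic reads to a three-level subsystem
    hierarchy by translated homology search against an identity-clustered
    protein reference, accelerated by reducing the reference on the fly to
    the subsystems carried by the genera that a k-mer/non-negative
    least-squares taxonomic profiler predicts in the sample. Includes a
    greedy identity clusterer for building reduced-redundancy databases, a
    built-in desk-scale translated aligner (plus an adapter for any
    external aligner producing BLAST tabular output), best-hit functional
    profiling at subsystem levels 1-3, an evaluation framework
    (sensitivity, precision, confusion matrices, hierarchical clustering
    of sample profiles), and a synthetic-community generator with known
    truth so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
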