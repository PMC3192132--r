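Package: rddaudit
Title: Auditing RNA-DNA Difference Calls for Genomic Explanations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing claimed RNA-DNA difference (RDD) sites for
    mundane genomic explanations. Calls RDD events from RNA-seq pileups with
    the standard coverage/purity/minor-fraction criteria, searches flanking
    sequence of each site against the reference genome for paralogs carrying
    the RDD nucleotide, tests per-individual genomic reads for the RDD
    nucleotide under lenient and stringent criteria with a nucleotide-swap
    specificity control, measures enrichment of sites in copy-number-variable
    regions by permutation, and extrapolates how many sites would be
    eliminated with additional individuals via rarefaction. Includes a
    synthetic cohort generator that plants reference paralogs, polymorphic
    paralogs, segregating duplications and genuine editing events with a
    ground-truth table, so the whole audit can be exercised end to end with
    known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
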