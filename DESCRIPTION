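Package: plrex
Title: Pseudo-Long Read Construction from Paired-End Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Connects Illumina-style paired-end short reads into pseudo-long
    reads by iteratively extending each read with the consensus of indel-free
    multiple sequence alignments until its mate is found. Candidate reads for
    each alignment window are retrieved from a minhash k-mer index built over
    the whole read set, placed by shifted Hamming-distance alignment, filtered
    by relative overlap and by a column-content rule that removes reads from
    inexact repeats, and stacked into a column-wise base-count alignment whose
    consensus drives the extension. Three strictness levels control how the
    two directional extensions of a pair are combined into the final
    pseudo-long read. The package also bundles a paired-end read simulator
    with known ground truth and the gap-accuracy evaluation metrics (gap
    error rate, modified edit distance, ambiguous-mate stratification) used
    to assess filled gaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
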