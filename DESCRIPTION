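Package: scploidy
Title: Single-Cell Whole-Genome Sequencing Aneuploidy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for calling whole-chromosome copy number in
    shallow single-cell whole-genome sequencing libraries, as used to screen
    neuronal nuclei for aneuploidy. Provides variable-width genomic binning
    driven by mappability, GC correction of per-bin read counts, an 11-state
    hidden Markov model with tied negative-binomial emissions fitted by
    Baum-Welch, five-metric library quality control with saturation-curve
    library-complexity estimation, whole-chromosome karyotyping with exact
    binomial prevalence intervals and rank-sum group comparisons, and a
    seeded synthetic-data generator that emulates shallow single-nucleus
    libraries so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
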