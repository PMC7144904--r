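Package: eotrscan
Title: Detection of Enhancer Occlusion Transcripts and Quantification of
    Transcriptional Interference at Enhancer Domains
Version: 0.1.0
Authors@R: person("eotrscan", "developers", role = c("aut", "cre"),
    email = "eotrscan@example.org")
Description: Tools to detect enhancer occlusion transcripts (EOTrs) -- capped,
    polyadenylated long non-protein-coding RNAs that run across enhancer
    domains and interfere with transcription factor binding -- and to quantify
    the resulting transcriptional interference. Provides chromatin-state
    classification from histone-mark peak combinations, a multi-stage
    transcript-filtering cascade, genome-structure-corrected association
    statistics (interval Jaccard with permutation nulls, relative-distance
    Kolmogorov-Smirnov, chi-squared), thermodynamic PWM occupancy modelling
    with binding-parameter fitting and occlusion-threshold detection,
    RNA-polymerase pausing indices from run-on coverage, allele-specific
    expression and enhancer-promoter loop analysis, simplified differential
    occupancy calls, and a seeded synthetic-locus generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
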