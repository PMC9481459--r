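Package: multicut
Title: Multi-Target CRISPR Guide Discovery and Cut-Site-Resolved Sequencing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing multi-target CRISPR guide RNAs
    (mgRNAs): enumeration of degenerate 20-nt guides from a repeat-element
    consensus template, PAM-anchored genome search for on-target sites,
    simulation of paired-end sequencing reads around cut sites with
    mappability (alignment-ambiguity) scoring, cut-site-resolved
    classification of paired-end fragments (span/abut categories and the four
    blunt-versus-staggered cleavage species), enrichment profiles and
    full-width-at-half-maximum measurement, fragment-length distributions with
    exponential-decay fitting, attribution of ChIP-seq peaks to the
    best-matching protospacer, amplicon editing-outcome classification with
    Shannon-entropy barcoding summaries, and a random-forest protocol linking
    epigenetic and mismatch features to enrichment. Deterministic synthetic
    fixture generators allow the whole pipeline to be exercised on synthetic
    genomes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    minpack.lm,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
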