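Package: spikefill
Title: Differential miRNA Expression and Grain-Filling Kinetics in Rice Spikelets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for small-RNA sequencing of superior and inferior
    rice spikelets across grain-filling stages. Implements an exact two-library
    count-comparison test (Audic-Claverie-type statistic) with tag-count
    normalization to transcripts per million, the zero-expression floor and
    low-abundance filter, fold-change classification of differentially expressed
    miRNAs, evidence-based acceptance criteria for novel miRNA candidates,
    logistic grain-filling kinetics with derived filling-rate curves, expression
    profile clustering and miRNA-target anti-correlation, and a synthetic-data
    generator that emulates the two-condition, five-stage study design with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
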