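Package: KacQuant
Title: Label-Free Quantification of Proteome and Lysine Acetylome
    Dynamics Across Growth Phases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing label-free mass-spectrometry experiments
    that profile a bacterial proteome and its N-epsilon-lysine acetylome
    across two growth phases. Implements peptide-spectrum-match filtering
    (Percolator q-value and Sequest XCorr thresholds), top-3 MS1-area
    protein quantification with a replicate-majority quantification-status
    rule, median normalization with global-minimum-zero scaling, in-silico
    tryptic digestion, aggregation of acetylated peptides into acetylation
    sites with oxidation-variant collapsing, estimation of log10
    acetylation abundance ratios against the matched total proteome,
    KEGG-style pathway coverage statistics with growth-phase fold changes,
    and a fully parameterised synthetic-data generator emulating the
    two-phase, three-replicate study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
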