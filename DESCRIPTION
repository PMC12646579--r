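Package: molphen
Title: Comparative Molecular Phenology of Seasonal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing seasonal (molecular phenology) transcriptome
    dynamics across species. Implements gene-length-corrected TMM (GeTMM)
    preprocessing of seasonal RNA-seq count series, a rank-based
    umbrella-alternative scan for rhythmic gene expression with an exact
    null distribution and adaptive Benjamini-Hochberg correction, circular
    peak-month statistics including a molecular phenology divergence index,
    cross-species expression-conservation summaries, Ward/WSS-elbow profile
    clustering, Nei-Gojobori (NG86) pairwise dN/dS estimation with
    Jukes-Cantor correction, and a seeded synthetic-data generator emulating
    multi-species four-weekly sampling designs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'clustering.R'
    'codons.R'
    'divergence.R'
    'dnds.R'
    'io.R'
    'normalize.R'
    'phenologyExperiment.R'
    'pipeline.R'
    'rhythm.R'
    'similarity.R'
    'simulate.R'
    'utils.R'
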