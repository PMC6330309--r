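Package: hcabrep
Title: Heavy-Chain-Only Antibody Repertoire Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of heavy-chain-only antibody (HCAb) discovery
    repertoires from immunized transgenic animals: germline V/J assignment
    and framework/CDR extraction for amino-acid VH sequences, somatic
    hypermutation counting, CDR3 clonotype clustering at 80% similarity,
    V-gene usage profiling with a decoy-based limit of detection, ELISA
    positivity calling, FR4 conserved-position versus light-chain-binding
    cross-tabulation, amino-acid-class composition statistics with
    Mann-Whitney tests, and Kyte-Doolittle hydropathy profiling. Includes a
    fully ground-truthed repertoire simulator so every pipeline stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'repertoire.R'
    'germline.R'
    'annotate.R'
    'clonotype.R'
    'composition.R'
    'simulate.R'
    'stats.R'
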