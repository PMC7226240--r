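Package: cementome
Title: Time-Course Proteomics of Tick Salivary Gland and Cement Secretomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for label-free (SWATH-type) protein
    quantitation of the tick salivary-gland proteome (sialome) and cement
    proteome (cementome) across adult female feeding stages. Provides Total
    Area Sums normalization, pairwise time-point differential representation
    tests, profile-based assignment of proteins to developmental-process
    categories, host/tick origin and tissue partition arithmetic, SparCC
    compositional co-occurrence networks with betweenness centrality,
    ProtParam-style physicochemical calculators (pI, GRAVY, instability and
    aliphatic indices, atomic composition), SEM-EDS elemental composition
    statistics, and alpha-Gal ELISA calibration and quantitation. Includes a
    synthetic-data generator with known ground truth that emulates the
    replicate structure of the study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
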