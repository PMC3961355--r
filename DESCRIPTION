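Package: dcnet
Title: Differential Connectivity of Gene Networks from Two-Condition
    Time-Course Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers genes whose co-expression network connectivity
    changes between two experimental conditions of a time-course
    microarray experiment, such as a light-dark cycle versus constant
    darkness in a circadian study. Profiles are replicate-averaged,
    min-max normalized to [-1, 1], screened by between-condition
    Euclidean distance with knee-point detection, transformed by a
    level-1 discrete wavelet transform (Mallat algorithm; Haar or
    Daubechies bases), and correlated in the frequency domain. A hard
    correlation threshold defines each condition's network; per-probe
    degree differences, their square ratios, and knee-based tail
    selection yield the key differentially connected probes. Includes a
    synthetic-data generator with planted co-expression modules, GEO
    series-matrix input, and TSV/GraphML export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
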