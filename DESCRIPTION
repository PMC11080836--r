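Package: dimerqc
Title: Adapter-Dimer Quality Control for Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pre- and post-sequencing quality control for small RNA
    sequencing libraries. Detects adapter-dimer contamination at the read
    level with an error-tolerant semi-global adapter matcher, classifies
    reads into dimer, short, low-quality and clean fractions, decomposes
    per-sample read loss, stratifies cohorts by piecewise linear
    regression on ordered read loss, locates dimer peaks in library
    electropherograms, and tests for dimer-driven batch effects on log2
    counts-per-million multidimensional scaling coordinates. Ships a
    seeded small RNA library simulator with ground truth that serves as
    the package's test harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    edgeR,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
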