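Package: sporometry
Title: Quantitative Image Analysis of Streptomyces Sporulation Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify sporulation phenotypes of filamentous
    Actinobacteria from microscopy images: focus-aware spore segmentation
    with particle filtering, measurement and classification of septum
    rotation angles (canonical, diagonal, longitudinal division planes),
    split-spore counting, per-spore DNA quantification with per-chain
    median normalization, two-channel live/dead classification,
    grey-level phenotyping of colony time-lapse scanner stacks, and
    single-exponential fitting of fluorescence recovery after
    photobleaching (FRAP) traces. Includes a seeded synthetic-microscopy
    generator with full ground truth so every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
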