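Package: charvoid
Title: Void Morphometry and Group Statistics for Charred Seed Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the internal hole structure of charred
    seeds imaged by X-ray computed tomography. Provides a synthetic phantom
    generator in which seed composition (protein and oil content), charring
    temperature and water saturation drive the expected population of
    internal voids; parallel-beam projection simulation with flat/dark-field
    correction and filtered back projection; 3D void segmentation with
    crack, break and outlier exclusion rules; normalized hole metrics,
    decade size categories and rank-size curves; and the group-comparison
    statistics used for such data (one-way ANOVA with a Levene gate to
    Fisher's LSD or Dunnett's T3, and two-tailed t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    tiff,
    withr,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
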