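Package: quadframe
Title: Quadtree Sampling Frames from Gridded Population Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds household-survey sampling frames from gridded population
    rasters by recursive quadtree decomposition into approximately
    population-homogeneous square units, following the design used for the
    Somali High Frequency Survey. Includes mass-conserving Gaussian smoothing
    of the population surface, uniform-grid-cell baseline frames with
    homogeneity diagnostics (standard deviation, coefficient of variation at
    national and regional scale), stratification by administrative region and
    population type, Neyman optimal allocation, with-replacement systematic
    probability-proportional-to-size selection of primary sampling units with
    replacement lists, multi-stage household selection, design weights with
    the Kish unequal-weighting effect, and a synthetic-data generator so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
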