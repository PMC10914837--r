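Package: gwqi
Title: Groundwater Quality Assessment with the Weighted-Arithmetic Water
    Quality Index, Hydrochemical Facies and Multivariate Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing drinking-water suitability of groundwater
    from major-ion chemistry. Implements the weighted-arithmetic Water
    Quality Index (unit weights inversely proportional to guideline
    standards, quality ratings scaled to 100 at the permissible limit, and
    the standard five quality bands), cation-anion charge-balance quality
    control in milliequivalents, Piper trilinear and Schoeller diagram
    coordinates with hydrochemical facies classification,
    correlation-matrix principal component analysis with Kaiser retention
    and varimax rotation, Spearman rank correlation, inverse-distance
    weighted interpolation of site values onto a regular grid, and a
    Gaussian-copula synthetic sample generator reproducing published
    marginal statistics and rank-correlation structure for a
    10-village x 5-sample survey design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
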