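Package: bat90
Title: Planar Yttrium-90 Source Dosimetry and Radiobiological Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models radio-ablation of the tumour bed after breast-conserving
    surgery with a planar yttrium-90 device. Provides a condensed-history
    Monte Carlo engine (and a point-kernel superposition backend) for the
    depth-dose of a uniform cylindrical beta source in homogeneous tissue,
    exponential parameterization of the depth-dose profile, activity planning
    for a prescription isodose at a chosen tissue depth, linear-quadratic
    surviving-fraction and tumour-control-probability models (Poisson and
    logistic via the equivalent uniform dose) under an exponentially decaying
    dose rate, and a TG-43-style transverse-axis fall-off comparison against
    conventional brachytherapy sources.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
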