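Package: incompair
Title: Confidence Intervals for a Mean Difference from Partially Paired Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Interval estimation for the difference of two means when some
    subjects contribute both measurements (complete pairs) and others
    contribute only one, as in crossover and pre/post designs with data
    missing completely at random. Implements large-sample intervals for known
    and estimated covariance (Lin-Stivers and Ekbohm type t statistics), a
    generalized-estimating-equations interval with sandwich variance, hybrid
    (MOVER-style) intervals that recover marginal variances from Wilson-score
    or Agresti-Coull limits, and simple and percentile block-bootstrap
    intervals. Includes a Monte-Carlo evaluation framework (coverage, width,
    mesial/distal non-coverage, power) for bivariate normal and bivariate
    t(5) populations, and the FEV1 formoterol crossover data as a worked
    example.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse, MASS, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
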