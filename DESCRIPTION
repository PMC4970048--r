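Package: graintex
Title: Weibull Texture Statistics and Semi-Supervised Grading of Granulated-Product Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture analysis and quality grading for images of granulated
    products (rice, seeds, fabric and similar stochastically packed scenes
    without a clean foreground/background split). Oriented image structure is
    measured by steerable Gaussian-derivative filtering: responses at any
    orientation are obtained as weighted sums of a small set of base filter
    responses. Per-orientation response histograms are modelled by a
    three-parameter integral-form Weibull distribution fitted by maximum
    likelihood (Nelder-Mead), and the fitted location/scale/shape triples over
    many directions, scales and subimages form the texture feature vector.
    Grading with scarce labels uses COSC-Boosting, a co-training loop in which
    a thin-plate-spline regression classifier and a multivariate adaptive
    regression splines classifier label confident unlabeled samples for each
    other. Includes seeded generators for granular-image and two-class
    semi-supervised benchmark fixtures, CSV/JSON/YAML serialization and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
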