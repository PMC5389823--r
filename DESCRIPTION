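Package: fragthresh
Title: Extinction Thresholds of Tree Communities Along Landscape Forest-Cover Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing how tree community attributes (species
    richness and abundance, overall and within families and functional-trait
    groups) respond to the amount of forest cover at the landscape scale.
    Implements multi-radius scale-of-effect selection by Spearman rank
    correlation, Monte-Carlo semivariogram envelope screening for spatial
    dependence, maximum-likelihood fitting and AICc ranking of four
    competing cover-response models (null, linear, power law and
    four-parameter logistic), extinction-threshold estimation as the
    logistic inflection point with profile-likelihood confidence intervals,
    spatial linear models (GLS with exponential covariance) for spatially
    structured responses, a forest-cover versus edge-distance covariate
    comparison dispatched to GLM, penalized-spline or spatial engines,
    correspondence analysis with segment detrending, and a synthetic
    community generator that emulates fragmented tropical-forest survey
    data so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    nlme,
    withr
Config/testthat/edition: 3
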