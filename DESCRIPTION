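Package: roadedge
Title: Edge-Effect Analysis of Dung Beetle Communities Along Logging Roads
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how far the ecological influence of unpaved logging
    roads penetrates into tropical forest, using baited-pitfall dung beetle
    communities as the model system. Implements the magnitude of edge
    influence (MEI) statistic with its randomization test (RTEI) and derived
    distance of edge influence (DEI), piecewise (breakpoint) negative-binomial
    gradient regressions selected by AIC, Bray-Curtis/NMDS community
    ordination with a multivariate bootstrap test of the edge-interior
    contrast, negative-binomial mixed models relating community metrics to
    standardized vegetation predictors with a Moran's I residual diagnostic,
    and landscape-scale road-edge area accounting. A synthetic trap-data
    generator reproduces the statistical structure of the underlying
    road-edge sampling design so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    glmmTMB,
    stats,
    utils,
    vegan
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
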