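Package: irmbridge
Title: Item Response Model Bridging of UPDRS and MDS-UPDRS Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graded-response item response model for Parkinson's disease
    rating-scale data that bridges the original UPDRS instrument onto item
    characteristic curves developed for the MDS-UPDRS revision. Implements
    three correlated latent disability variables (patient-reported,
    non-sided and sided clinician-rated items), a two-class mixture for the
    more disabled body side, probability reassignment for indirectly mapped
    items, population shift parameters for early versus advanced disease,
    linear latent progression over time, marginal maximum likelihood via
    Laplace approximation or adaptive Gauss-Hermite quadrature, empirical
    Bayes latent estimates, a synthetic trial generator, and
    simulation-based diagnostics (item mean checks, residual correlations,
    visual predictive checks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, pracma
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
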