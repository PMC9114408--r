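Package: catgrm
Title: Graded Response Model Calibration and Computerized Adaptive Testing
    for Patient-Reported Depression Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates item banks for latent-trait measurement of
    depression severity from ordinal questionnaire data.  Implements the full
    development workflow: classical item screening (Cronbach's alpha,
    item-remainder correlations, unanswered categories), checks of the item
    response theory assumptions (principal-component unidimensionality,
    one-factor residual correlations for local independence, Loevinger
    scalability coefficients for monotonicity), marginal maximum likelihood
    calibration of the graded response model by EM, latent-trait scoring
    (maximum likelihood, Bayesian modal, expected a posteriori), S-X2 item
    fit, likelihood-ratio tests of differential item functioning,
    computerized adaptive testing simulation with Fisher-information and
    Kullback-Leibler item selection, and fixed-parameter calibration of
    legacy short forms onto the bank's latent scale.  A synthetic-cohort
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'itemBank.R'
    'responseMatrix.R'
    'io.R'
    'grm-probs.R'
    'grm-fit.R'
    'grm-score.R'
    'grm-sx2.R'
    'grm-dif.R'
    'synth.R'
    'screening.R'
    'cat.R'
    'calibrate.R'
    'pipeline.R'
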