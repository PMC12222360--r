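Package: habsel
Title: Two-Stage Habitat-Selection Inference from Prey Surveys and Carnivore Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for landscape-scale habitat-selection analysis of large
    carnivores in two linked stages. Stage one fits single-season occupancy
    models to replicated track-survey detection histories, including the
    Royle-Nichols abundance-induced heterogeneous detection model, the
    MacKenzie constant-detection model and a Markovian spatial-dependence
    comparator, with AICc-based replicate-length selection, univariate
    screening, collinearity filtering, all-subsets ranking, conditional
    model averaging and parametric-bootstrap goodness of fit, yielding
    relative prey-abundance surfaces. Stage two builds used-available
    resource selection designs from GPS telemetry (kernel utilization
    distributions with plug-in bandwidths, 95 percent isopleth home ranges,
    demographic classing) and fits logistic mixed-effects resource
    selection functions with demographic-class interactions, likelihood
    ratio term deletion, odds-ratio reporting and per-class selection maps.
    A synthetic-landscape generator with recorded ground truth makes every
    stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, lme4, KernSmooth, jsonlite, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
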