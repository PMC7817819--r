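Package: ccistiff
Title: EMG Co-Contraction Indices as Surrogates for Model-Based Joint Stiffness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well EMG-based co-contraction indices
    (CCIs) approximate sagittal-plane joint stiffness during gait. Implements
    the standard EMG linear-envelope pipeline with four signal variants
    (basic, scaled, delayed, calibrated), the Rudolph and Falconer-Winter CCI
    formulations over antagonist muscle pairs, analytic joint stiffness from a
    rigid-tendon Hill-type musculotendon model with polynomial musculotendon
    geometry, and per-gait-cycle Pearson correlation with Wilcoxon rank-sum
    comparisons. Includes a synthetic virtual-subject generator with known
    ground truth so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
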