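Package: tractage
Title: Tract-Specific White-Matter Brain Age and Brain-Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Normative modelling of white-matter development from along-tract
    fractional anisotropy (FA) profiles. Fits per-tract and whole-brain
    Gaussian-process age models, derives bias-corrected brain-age gaps (BAGs),
    harmonizes multi-site tract profiles with empirical-Bayes ComBat, links
    BAGs to cognitive and psychopathology measures through sparse canonical
    correlation (penalized matrix decomposition) with permutation and
    bootstrap inference, relates BAGs to psychiatric diagnosis counts,
    diagnostic transitions, puberty and salivary hormones through GLM, GAM and
    mixed-model analyses, and decodes tract loading patterns against
    volumetric functional and mitochondrial maps using
    spatial-autocorrelation-preserving surrogate nulls. Includes a synthetic
    cohort generator with planted developmental structure so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    lme4,
    lmerTest,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    emmeans,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
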