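Package: molarDrift
Title: Three-Dimensional Measurement of Overeruption and Tipping of
    Unopposed Molars from CBCT-Style Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the three-dimensional positional change of a
    molar that has lost its antagonist, following the cone-beam computed
    tomography (CBCT) measurement workflow used in short-term implant
    rehabilitation studies: multi-threshold segmentation of crown, root and
    alveolar bone into a combined surface model; masked best-fit rigid
    superimposition of follow-up onto baseline by the iterative closest
    point algorithm; construction of a tooth-local coordinate frame from
    the occlusal plane and marginal-crest landmarks; mean and maximum cusp
    overeruption with cusp attribution and bucco-lingual/mesio-distal
    tipping changes; and the accompanying statistics layer (one-sample t,
    one-way ANOVA across molar types, descriptive frequency tables,
    Dahlberg method error, two-way mixed intraclass correlation). A
    synthetic two-timepoint molar phantom generator with known ground-truth
    motion makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
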