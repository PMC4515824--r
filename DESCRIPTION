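Package: leukarray
Title: Simulation and Quantification of Anti-CD Antibody Leukocyte-Capture Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates anti-cluster-of-differentiation (anti-CD) antibody
    microarrays that capture peripheral blood mononuclear cells on antibody
    spots, and quantifies the result the way a hematology laboratory would:
    saturation-binding titration fits with a shared characteristic
    concentration, cell counting and density estimation on rendered
    microscopy-like spot images, nuclear morphometry (nuclear contour index,
    cleft detection, nuclear-cytoplasmic ratio), rule-based leukocyte
    morphotype classification, normalized-density immunophenotyping with
    flow-cytometry concordance, morphotype-by-antibody cross-tabulation, and
    reference-interval flagging with leukemia binding-pattern signatures
    (CLL, HCL, SMZL, MCL, FL). A synthetic cohort generator with analytically
    known per-cell geometry provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
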