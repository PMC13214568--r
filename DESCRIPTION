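Package: odfreweight
Title: Cross-Subject Variance Reweighting of Fiber Orientation
    Distributions for Crossing-Fiber Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to diagnose and correct anterior-posterior orientation
    bias in diffusion MRI fiber orientation distribution functions (fODFs).
    Implements the axial orientation-angle statistic phi, cross-subject
    standard-deviation reweighting of fODF fields, orientation-angle change
    histograms, a minimal deterministic/probabilistic streamline tracker
    with tissue-based stopping, streamline-density summaries, and a
    synthetic multi-subject crossing-fiber phantom that reproduces the
    suppression and recovery of a weak medial-lateral bundle under a
    dominant anterior-posterior bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
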