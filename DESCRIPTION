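Package: cbctrepair
Title: Repairing Partially Acquired Cone-Beam CT with Conditional
    Adversarial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and repairing partially acquired
    cone-beam computed tomography (CBCT) used in radiotherapy patient
    setup. Provides a seeded thorax phantom generator, a synthetic-CBCT
    simulator that injects streak artifacts by sinogram-domain
    replacement and truncates the circular field of view, a
    clinical-style preprocessing chain (zero padding, rigid
    registration, couch removal), a pix2pix-style conditional
    adversarial image-translation model with patient-specific transfer
    learning of the final layers, and SSIM/MAE evaluation with
    volume-level summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
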