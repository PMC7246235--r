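Package: petacgan
Title: Independent PET Attenuation Correction via Pseudo-CT Synthesis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale, fully testable pipeline for independent whole-body
    PET attenuation correction. A conditional generative adversarial network
    translates non-attenuation-corrected PET slices into pseudo-CT images,
    which are converted to 511-keV attenuation maps and used in iterative
    (MLEM/OSEM) reconstruction. Includes a synthetic paired-phantom generator
    with respiratory-mismatch and bowel-gas scenarios, a parallel-beam
    attenuated projector, SUV quantification with circular ROIs and 50
    percent isocontour VOIs, voxel-wise difference maps, Bland-Altman
    agreement and box-plot summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
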