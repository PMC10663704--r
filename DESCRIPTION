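Package: mammocad
Title: Mammographic Mass Detection on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A computer-aided detection pipeline for breast masses in
    grayscale mammograms, exercised end-to-end on synthetic phantoms.
    Provides PGM image input/output and a parser for the standard
    seven-column mammogram metadata table; a labelled phantom generator
    with injectable salt-and-pepper, Gaussian and Poisson noise; wavelet
    shrinkage denoising driven by a greedy local search over a total
    variation plus fidelity energy; morphological mass segmentation
    (hand-authored erosion, dilation and boundary operators plus a
    two-feature K-segment clustering); a classifier built from a frozen
    random convolution stack with an atrous (dilated) pyramid, trained in
    closed form by Moore-Penrose pseudoinverse, with dense-CRF mean-field
    refinement of the mass mask and particle-filter localization of the
    mass center; and an evaluation harness (PSNR, MSE, Dice, ROC/AUC,
    stratified splits and k-fold cross-validation) with a scriptable
    pipeline entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
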