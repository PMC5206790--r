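Package: vtumour
Title: Hybrid Multiscale Simulation of Vascular Tumour Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A hybrid cellular-automaton model of tumour growth coupled to
    reaction-diffusion fields (VEGF, oxygen and two protease species), an
    implicit capillary field with a discrete vessel network, sprouting
    angiogenesis, and hemodynamic initialization of vessel diameters by
    iterative adaptation under Poiseuille flow. Virtual tumours are
    initialized from grayscale fluorescence-style images (three-level
    density thresholding) and vessel polylines, or from a built-in
    synthetic case generator. Includes the growth-curve, texture-histogram
    and proliferative-fraction analyses used to locate the angiogenic
    bottleneck, the period in which integral-normalized growth curves of
    different tumours converge.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Matrix,
    Rcpp,
    yaml,
    png,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
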