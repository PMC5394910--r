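Package: nsctfusion
Title: Adaptive PCNN Fusion of PET and CT Images in the Nonsubsampled
    Contourlet Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fuses co-registered whole-body PET and CT slices by decomposing
    both images with a shift-invariant nonsubsampled contourlet transform
    (NSCT), driving a simplified pulse-coupled neural network (PCNN) per
    subband with novel sum-modified Laplacian (low-pass) and energy-of-edge
    (high-pass) feature maps, selecting coefficients by the max-region-energy
    rule on the PCNN firing maps, and inverting the transform. Includes
    discrete-wavelet and NSCT max-rule baselines, seven fusion quality
    metrics (average gradient, Shannon/joint/cross entropy, image quality
    index, edge-dependent quality Q_E, and edge-preservation Q^AB/F), a
    seeded synthetic PET/CT phantom generator, grayscale image readers and
    writers (PNG, TIFF, NIfTI), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    jsonlite,
    png,
    tiff,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
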