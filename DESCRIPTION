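Package: histostack
Title: Serial-Section Histology Registration, 3D Reconstruction and Coagulation-Lesion Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale pipeline for reconstructing small-animal eye anatomy from
    serial histological sections. Provides foreground segmentation of slices with
    point-prompt component selection, rigid 2D slice-to-slice registration under four
    strategies (unregistered, on the original RGB, on the segmented RGB, on the binary
    mask), stack-coherence evaluation by masked MSE and SSIM against a moving average
    of adjacent slices, calibrated volume assembly with orthogonal sectional views,
    retinal coagulation-lesion morphometry (lesion diameter, six-point scar and
    baseline thickness, thickness ratio, species-specific shrinkage correction), and
    group statistics from summary data (Student/Welch t-tests, Hedge's g, two-way
    ANOVA with Holm-Sidak post-hoc tests). A synthetic serial-section generator with
    known ground truth makes every stage testable without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    car,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
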