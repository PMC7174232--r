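Package: budvision
Title: Computer-Vision Morphometrics and Classification of Dried Flower Buds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading dried chrysanthemum tea buds from plate images.
    Implements two complementary pipelines: a morphological branch
    (median denoising, Otsu segmentation, contour tracing, fourteen contour
    shape descriptors, PCA and grid-searched KNN/MLP/SVM classification of
    flowering stage and product type) and a raw-image branch (finder-pattern
    detection, perspective rectification, bicubic 50x50 crops and a compact
    convolutional network trained with RMSProp). Because no public image set
    exists for this task, the package ships a synthetic plate-image generator
    with analytic ground truth (masks, labels and closed-form morphology for
    canonical shapes) that emulates both acquisition setups: backlit 16-bit
    grayscale gel-imager plates and hand-held 8-bit colour phone shots with
    perspective distortion, uneven illumination and shadow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp,
    jsonlite,
    tiff,
    png,
    e1071,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
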