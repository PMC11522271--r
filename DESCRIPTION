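Package: dtwstrain
Title: Tracking-Free Left Ventricular Strain from Segmentation Masks via
    Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes left-ventricular (LV) longitudinal strain directly from
    a temporally ordered sequence of binary myocardial segmentation masks,
    with no speckle or feature tracking. Each frame is processed
    independently: the myocardial boundary is traced, the two mitral-annular
    endpoints and the apex are located from the mask skeleton and an ellipse
    fit, the endocardial and epicardial contours are resampled to a fixed
    point count, and dynamic time warping pairs the two layers into
    triangular/rectangular units that are merged into 60 serially numbered
    blocks under proportional area conservation anchored at end-diastole.
    The centerline through the 61 block-border midpoints yields the
    Lagrangian strain curve, peak strain, and six-segment regional strain;
    end-diastole is re-detected per cardiac cycle so multi-beat videos are
    supported. Includes a registration-consistency ("hopscotch") metric for
    externally tracked points and a deforming U-shaped phantom generator
    with analytic ground-truth strain for validation.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    mgcv,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
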