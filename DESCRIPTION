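Package: tlcscreen
Title: Smartphone-Style Thin-Layer Chromatography Densitometry for Drug
    Quality Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies spots on photographs of thin-layer
    chromatography (TLC) plates imaged under UV illumination, as used in
    point-of-care screening of substandard and falsified medicines. The
    pixel pipeline (green-channel extraction, min-max inversion, Gaussian
    smoothing, grayscale dilation, Otsu thresholding, 8-connected contour
    detection and per-spot area-under-the-curve) yields retention factors
    and densitometric signals; a linear calibration model with ICH-style
    limits of detection and quantification converts signals to drug
    concentration and per-tablet active-ingredient content, rendering
    pharmacopeial pass/substandard verdicts. A ground-truthed synthetic
    plate renderer, quality-control statistics (repeatability, recovery,
    method agreement) and a command-line interface complete the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
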