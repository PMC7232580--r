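Package: ecgclust
Title: Clustering of ECG Morphology Features Against Chronic Disease Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring associations between electrocardiogram (ECG)
    morphology and chronic conditions (diabetes, obesity, hypertension,
    smoking) by unsupervised clustering. Provides a labeled synthetic ECG
    cohort generator with realistic beat morphology and noise classes, FIR
    band-pass denoising, derivative-based QRS detection and beat
    segmentation, three feature extractors (reduced binary pattern symbolic
    dynamics, R-R-segmented discrete wavelet coefficients, and a 24-element
    waveform fiducial descriptor), a native Lloyd k-means implementation,
    and cluster-association metrics (per-group ratio and concentricity)
    with cross-tabulated reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
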