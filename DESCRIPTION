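Package: pocte
Title: Simulation and Diagnostic Accuracy Analysis for Imaging-Guided
    Point-of-Care Transient Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an imaging-guided point-of-care transient elastography
    (TE) exam end to end on layered tissue phantoms: shear-wave propagation and
    radiofrequency (RF) speckle acquisition, elastogram construction with
    rule-based quality control and wave-trajectory detection yielding liver
    stiffness (kPa), and a reference-phantom spectral method yielding a
    multi-domain attenuation parameter (dB/m at 3.5 MHz) with parenchyma
    masking and calibration. Implements the exam protocol (skin-to-capsule
    distance driven acquisition-mode selection, ten valid measurements, median
    reporting), a synthetic biopsy-cohort generator with paired-device
    measurements and serum fibrosis/steatosis scores, and the accompanying
    diagnostic-accuracy toolkit: ROC/AUROC with DeLong variance and paired
    tests, Youden and fixed-operating-point cutoffs, Bland-Altman limits of
    agreement, intraclass correlation, weighted kappa, Kruskal-Wallis with
    Dunn post hoc, and a repeated-measurement sufficiency analysis over median
    subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
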