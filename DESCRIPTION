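Package: passivebci
Title: Passive Brain-Computer Interface Neurometrics from EEG Band Powers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for passive brain-computer interface (BCI)
    studies that monitor mental workload, stress and vigilance from
    low-density frontal/parietal EEG. Provides a synthetic multi-condition
    EEG session generator with known ground truth, preprocessing
    (Butterworth band-pass, blink detection, multi-channel Wiener-filter
    ocular correction, 1-s epoching, amplitude-threshold artifact
    rejection), spectral analysis (Welch power spectral densities,
    individual-alpha-frequency estimation, IAF-anchored and fixed band
    schemes, band-integrated global field power), formula-defined
    workload/stress/vigilance neurometrics, per-subject Random-Forest
    classifier calibration with ADASYN class balancing and AUC evaluated
    as a function of temporal resolution (including run-split, k-fold and
    cross-task schemes), and a two-system signal-quality comparison
    (impedance drift, artifact percentages, per-band spectral correlation
    with Bonferroni thresholds, exact Wilcoxon signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
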