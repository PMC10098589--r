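Package: mrsfpc
Title: Frequency and Phase Correction of MR Spectroscopy Transients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for frequency and phase correction (FPC) of magnetic
    resonance spectroscopy (MRS) transients before averaging. Implements
    classical comparators (time-domain spectral registration, windowed
    spectral registration, frequency-domain correlation, creatine
    referencing), an unsupervised physics-informed autoencoder whose
    decoder is an analytic signal model (Lorentzian creatine fit or
    reference-shift model), k-means selection of the reference scan, a
    synthetic transient generator with known ground truth, and evaluation
    metrics (precision, similarity index, creatine linewidth, SNR sweeps,
    Monte Carlo studies).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, data.table, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
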