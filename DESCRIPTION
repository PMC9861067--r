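Package: ssavmd
Title: Non-Contact Vital-Sign Extraction from UWB Impulse Radar by SSA and VMD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts respiration and heartbeat rates from ultra-wideband
    impulse radar echo matrices. Implements the full processing chain:
    singular-value-decomposition clutter suppression, maximum-energy range
    gate selection, singular spectrum analysis (SSA) denoising of the
    slow-time vital-sign signal, variational mode decomposition (VMD) into
    narrowband intrinsic mode functions by ADMM in the frequency domain, and
    spectral rate estimation with respiratory-harmonic rejection. Includes a
    physics-based echo simulator (dual-sinusoid chest motion, first-order
    Gaussian pulse, static clutter, DC offset, additive noise) so the whole
    pipeline is testable without radar hardware, plus per-subject error
    reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
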